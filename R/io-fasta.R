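#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; IUPAC ambiguity
#' codes are preserved as-is and record order follows the file.
#'
#' @param path path to a FASTA file.
#' @return tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records")
  empty <- which(Biostrings::width(set) == 0)
  if (length(empty) > 0) {
    stop("empty sequence in FASTA record(s) ",
         paste(empty, collapse = ", "), " of '", path, "'")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("malformed header in FASTA record(s) ",
         paste(which(!nzchar(ids)), collapse = ", "), " of '", path, "'")
  }
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(set))))
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with columns `id` and `sequence` (a `references` tibble
#'   with `gene_id` works too), or a named character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) {
    x <- tibble::tibble(id = names(x), sequence = unname(x))
  }
  if (!"id" %in% names(x) && "gene_id" %in% names(x)) {
    x <- dplyr::rename(x, id = "gene_id")
  }
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read one FASTQ file (sequences only)
#'
#' Base qualities are not used by the pipeline and are dropped on read.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return tibble with columns `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(id = sub("\\s.*$", "", names(set)),
                 sequence = unname(as.character(set)))
}

#' Write paired-end reads to R1/R2 FASTQ files
#'
#' @param reads tibble with columns `read_id`, `mate` (1 or 2), `sequence`.
#' @param r1_path,r2_path output paths.
#' @return invisible character vector of the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(d, p) {
    set <- Biostrings::DNAStringSet(d$sequence)
    names(set) <- d$read_id
    Biostrings::writeXStringSet(set, p, format = "fastq")
    p
  }
  r1 <- write_one(reads[reads$mate == 1L, ], r1_path)
  r2 <- write_one(reads[reads$mate == 2L, ], r2_path)
  invisible(c(r1, r2))
}
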