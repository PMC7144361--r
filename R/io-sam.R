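#' Serialize mapped placements to a minimal SAM file
#'
#' One line per mapped read, minimal `@HD`/`@SQ` header, CIGAR `<len>M`.
#' Reverse-strand placements are written with FLAG 16 and SEQ already
#' reverse-complemented, as the SAM convention requires.
#'
#' @param placements tibble in the [map_reads()] layout.
#' @param references tibble from [reference_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, references, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      references$gene_id, references$length))
  p <- placements[which(placements$mapped), ]
  body <- character(0)
  if (nrow(p) > 0) {
    flag <- ifelse(p$strand == "-", 16L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                    p$read_id, flag, p$gene_id, p$start + 1L,
                    nchar(p$query), p$query)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Ingest a SAM file into one sample's pileup
#'
#' Per-site base counts are incremented only for aligned query bases over
#' reference positions: CIGAR `M`, `=` and `X` consume both sequences and are
#' counted; `I` and `S` consume the query only and are skipped; `D` consumes
#' the reference only and contributes nothing. Unmapped (flag 0x4) and
#' secondary (0x100) or supplementary (0x800) records are ignored. SEQ is
#' counted as stored (SAM stores reverse-strand reads already
#' reverse-complemented).
#'
#' @param path path to a SAM file.
#' @param references tibble from [reference_genes()]; `@SQ` names must match
#'   `gene_id`s.
#' @param sample_id sample label attached to the result.
#' @return pileup tibble as from [pileup_from_placements()].
#' @export
ingest_sam <- function(path, references, sample_id = NA_character_) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  unknown <- setdiff(sq_names, references$gene_id)
  if (length(unknown) > 0) {
    stop("SAM reference name(s) absent from references: ",
         paste(unknown, collapse = ", "))
  }
  counts <- lapply(references$length, function(L) {
    m <- matrix(0L, nrow = L, ncol = 5L)
    colnames(m) <- c("A", "C", "G", "T", "other")
    m
  })
  names(counts) <- references$gene_id
  body_idx <- which(!is_header)
  for (ln in body_idx) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record at line ", ln)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next        # unmapped
    if (bitwAnd(flag, 256L) != 0L) next      # secondary
    if (bitwAnd(flag, 2048L) != 0L) next     # supplementary
    rname <- f[3]
    if (!rname %in% references$gene_id) {
      stop("SAM record at line ", ln, " maps to unknown reference '",
           rname, "'")
    }
    pos0 <- as.integer(f[4]) - 1L
    cigar <- f[6]
    seq <- toupper(f[10])
    ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
    if (cigar == "*" || length(ops) == 0 ||
        nchar(paste0(ops, collapse = "")) != nchar(cigar)) {
      stop("malformed CIGAR '", cigar, "' at line ", ln)
    }
    op_len <- as.integer(sub("[A-Z=]$", "", ops))
    op_chr <- sub("^[0-9]+", "", ops)
    bad <- !op_chr %in% c("M", "=", "X", "I", "D", "S")
    if (any(bad)) {
      stop("unsupported CIGAR operation '", op_chr[bad][1], "' at line ", ln)
    }
    qpos <- 0L; rpos <- pos0
    L <- references$length[match(rname, references$gene_id)]
    for (i in seq_along(op_chr)) {
      len <- op_len[i]
      switch(op_chr[i],
        "M" = , "=" = , "X" = {
          sites <- rpos + seq_len(len)        # 1-based rows
          if (any(sites < 1L | sites > L)) {
            stop("alignment overruns reference at line ", ln)
          }
          b <- base_column_lut[
            as.integer(charToRaw(substring(seq, qpos + 1L, qpos + len))) + 1L]
          for (j in seq_len(len)) {
            counts[[rname]][sites[j], b[j]] <- counts[[rname]][sites[j], b[j]] + 1L
          }
          qpos <- qpos + len; rpos <- rpos + len
        },
        "I" = , "S" = { qpos <- qpos + len },
        "D" = { rpos <- rpos + len }
      )
    }
  }
  tibble::tibble(gene_id = references$gene_id, sample_id = sample_id,
                 counts = unname(counts[references$gene_id]))
}
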