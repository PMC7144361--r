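#' Read and validate an RNA-editing site catalogue
#'
#' The catalogue lists genomic positions known to be post-transcriptionally
#' edited in the reference organelle transcriptomes. On disk positions are
#' 1-based (TSV columns `gene_id`, `position_1based`, `genomic_base`,
#' `edited_base`); internally the package uses 0-based coordinates. Every row
#' is validated against the reference sequence it names.
#'
#' @param path path to the TSV catalogue.
#' @param references tibble from [reference_genes()].
#' @return tibble with columns `gene_id`, `position` (0-based),
#'   `genomic_base`, `edited_base`.
#' @export
read_editing_catalogue <- function(path, references) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           position_1based = readr::col_integer(),
                           genomic_base = readr::col_character(),
                           edited_base = readr::col_character()
                         ))
  need <- c("gene_id", "position_1based", "genomic_base", "edited_base")
  if (!all(need %in% names(tbl))) {
    stop("editing catalogue must have columns ", paste(need, collapse = ", "))
  }
  validate_editing_catalogue(
    tibble::tibble(gene_id = tbl$gene_id,
                   position = tbl$position_1based - 1L,
                   genomic_base = toupper(tbl$genomic_base),
                   edited_base = toupper(tbl$edited_base)),
    references
  )
}

#' Validate an in-memory editing catalogue (0-based positions)
#' @keywords internal
validate_editing_catalogue <- function(cat, references) {
  problems <- character(0)
  gi <- match(cat$gene_id, references$gene_id)
  bad_gene <- which(is.na(gi))
  if (length(bad_gene)) {
    problems <- c(problems, paste0("row ", bad_gene, ": unknown gene_id '",
                                   cat$gene_id[bad_gene], "'"))
  }
  ok <- !is.na(gi)
  len <- references$length[gi]
  bad_pos <- which(ok & (cat$position < 0L | cat$position >= len))
  if (length(bad_pos)) {
    problems <- c(problems, paste0("row ", bad_pos, ": position out of range"))
  }
  in_range <- ok & cat$position >= 0L & !is.na(len) & cat$position < len
  ref_base <- rep(NA_character_, nrow(cat))
  ref_base[in_range] <- substring(references$sequence[gi[in_range]],
                                  cat$position[in_range] + 1L,
                                  cat$position[in_range] + 1L)
  bad_base <- which(in_range & ref_base != cat$genomic_base)
  if (length(bad_base)) {
    problems <- c(problems,
                  paste0("row ", bad_base, ": genomic_base ",
                         cat$genomic_base[bad_base],
                         " does not match reference base ",
                         ref_base[bad_base]))
  }
  bad_same <- which(cat$genomic_base == cat$edited_base)
  if (length(bad_same)) {
    problems <- c(problems,
                  paste0("row ", bad_same, ": genomic_base equals edited_base"))
  }
  if (anyDuplicated(cat[c("gene_id", "position")])) {
    dup <- which(duplicated(cat[c("gene_id", "position")]))
    problems <- c(problems, paste0("row ", dup, ": duplicated (gene, position)"))
  }
  if (length(problems)) {
    stop("invalid editing catalogue:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cat
}

#' Write an editing catalogue as 1-based TSV
#'
#' @param catalogue tibble with 0-based `position` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_editing_catalogue <- function(catalogue, path) {
  out <- tibble::tibble(gene_id = catalogue$gene_id,
                        position_1based = catalogue$position + 1L,
                        genomic_base = catalogue$genomic_base,
                        edited_base = catalogue$edited_base)
  readr::write_tsv(out, path)
  invisible(path)
}
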