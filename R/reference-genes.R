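#' Build a validated table of reference organelle genes
#'
#' A reference gene is one organelle coding sequence together with the
#' metadata the downstream analysis needs: which genome compartment it comes
#' from (mitochondrial `"mt"` or plastid `"pt"`), the reading-frame offset of
#' the first complete codon, and the NCBI translation table used to decide
#' synonymous versus nonsynonymous changes.
#'
#' @param gene_id character vector of short gene names (e.g. `"cox1"`).
#' @param compartment `"mt"` or `"pt"`, recycled if length 1.
#' @param sequence DNA strings over `A/C/G/T` (lower case accepted).
#' @param frame_offset integer 0..2, offset of the first complete codon.
#' @param translation_table_id NCBI genetic-code table number (default 1).
#' @param complete_cds logical; when `TRUE` (default) the in-frame length must
#'   be divisible by 3.
#'
#' @return A tibble with one row per gene and columns `gene_id`,
#'   `compartment`, `sequence`, `length`, `frame_offset`,
#'   `translation_table_id`, `complete_cds`.
#' @export
reference_genes <- function(gene_id, compartment, sequence,
                            frame_offset = 0L,
                            translation_table_id = 1L,
                            complete_cds = TRUE) {
  sequence <- toupper(sequence)
  n <- length(gene_id)
  tbl <- tibble::tibble(
    gene_id = as.character(gene_id),
    compartment = rep_len(as.character(compartment), n),
    sequence = sequence,
    length = nchar(sequence),
    frame_offset = rep_len(as.integer(frame_offset), n),
    translation_table_id = rep_len(as.integer(translation_table_id), n),
    complete_cds = rep_len(as.logical(complete_cds), n)
  )
  if (anyDuplicated(tbl$gene_id)) stop("duplicated gene_id in references")
  if (!all(tbl$compartment %in% c("mt", "pt"))) {
    stop("compartment must be 'mt' or 'pt'")
  }
  if (any(grepl("[^ACGT]", tbl$sequence))) {
    stop("reference sequences must contain only A/C/G/T")
  }
  if (any(tbl$length < 3)) stop("reference sequences must be >= 3 bp")
  if (!all(tbl$frame_offset %in% 0:2)) stop("frame_offset must be 0, 1 or 2")
  bad <- tbl$complete_cds & ((tbl$length - tbl$frame_offset) %% 3L != 0L)
  if (any(bad)) {
    stop("complete-CDS genes must have in-frame length divisible by 3: ",
         paste(tbl$gene_id[bad], collapse = ", "))
  }
  tbl
}

#' Look up one reference row by gene id
#' @keywords internal
ref_row <- function(references, gene_id) {
  i <- match(gene_id, references$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  references[i, ]
}
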