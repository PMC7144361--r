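#' Call the representative (dominant-nucleotide) sequence of one pileup
#'
#' At each site with depth at least `min_depth`, the base with the highest
#' count wins; ties are broken in favour of the reference base when it is
#' among the tied set, else the lexicographically smallest base. Sites below
#' `min_depth` (or with only non-ACGT counts) are written `N` and are treated
#' as missing downstream: missing data must not masquerade as the reference
#' allele.
#'
#' @param counts `L x 5` pileup count matrix (columns `A,C,G,T,other`).
#' @param reference one-row reference tibble (or the full references tibble
#'   plus `gene_id`).
#' @param gene_id gene to look up when `reference` has several rows.
#' @param min_depth minimum depth for a call (default 1).
#' @return list with `sequence` (string over `A/C/G/T/N` of reference length)
#'   and `covered_fraction` (share of sites with depth >= 1).
#' @export
call_representative <- function(counts, reference, gene_id = NULL,
                                min_depth = 1L) {
  if (nrow(reference) > 1) reference <- ref_row(reference, gene_id)
  L <- reference$length
  if (nrow(counts) != L) {
    stop("pileup has ", nrow(counts), " rows but reference '",
         reference$gene_id, "' has length ", L)
  }
  acgt <- counts[, 1:4, drop = FALSE]
  depth <- rowSums(counts)
  mx <- pmax(acgt[, 1], acgt[, 2], acgt[, 3], acgt[, 4])
  pick <- max.col(acgt, ties.method = "first")  # lexicographically smallest
  refc <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  ref_idx <- match(refc, DNA_BASES)
  ref_tied <- acgt[cbind(seq_len(L), ref_idx)] == mx
  pick[ref_tied] <- ref_idx[ref_tied]
  base <- DNA_BASES[pick]
  base[depth < min_depth | mx == 0L] <- "N"
  list(sequence = paste0(base, collapse = ""),
       covered_fraction = mean(depth >= 1L))
}

#' Call representative sequences for a whole pileup table
#'
#' @param pileups tibble with columns `gene_id`, `sample_id`, `counts`
#'   (as produced by [pileup_sample()] rows bound together).
#' @param references tibble from [reference_genes()].
#' @param min_depth minimum depth for a call.
#' @return tibble with columns `gene_id`, `sample_id`, `sequence`,
#'   `covered_fraction`.
#' @export
call_representatives <- function(pileups, references, min_depth = 1L) {
  res <- purrr::pmap(
    list(pileups$counts, pileups$gene_id),
    function(cnt, g) call_representative(cnt, references, g, min_depth)
  )
  tibble::tibble(
    gene_id = pileups$gene_id,
    sample_id = pileups$sample_id,
    sequence = vapply(res, `[[`, character(1), "sequence"),
    covered_fraction = vapply(res, `[[`, numeric(1), "covered_fraction")
  )
}

#' Compartment-wide covered fraction per sample
#'
#' The covered fraction is the share of all coding sites of a compartment
#' (across its genes) with read depth >= 1 in that sample.
#'
#' @param pileups pileup tibble (`gene_id`, `sample_id`, `counts`).
#' @param references tibble from [reference_genes()].
#' @return tibble with columns `sample_id`, `compartment`,
#'   `covered_fraction`.
#' @export
compartment_coverage <- function(pileups, references) {
  comp <- stats::setNames(references$compartment, references$gene_id)
  d <- tibble::tibble(
    sample_id = pileups$sample_id,
    compartment = unname(comp[pileups$gene_id]),
    covered = vapply(pileups$counts, function(m) sum(rowSums(m) >= 1),
                     numeric(1)),
    sites = vapply(pileups$counts, nrow, numeric(1))
  )
  dplyr::summarise(dplyr::group_by(d, .data$sample_id, .data$compartment),
                   covered_fraction = sum(.data$covered) / sum(.data$sites),
                   .groups = "drop")
}

#' Filter out low-coverage samples per compartment
#'
#' A sample is retained for a compartment iff its compartment-wide covered
#' fraction is at least `threshold`. Filtering is per compartment: a sample
#' may be retained for the mitochondrial analysis and dropped from the
#' plastid one, or vice versa.
#'
#' @param coverage tibble from [compartment_coverage()].
#' @param threshold minimum covered fraction (default 0.90).
#' @return the input with a logical `retained` column added.
#' @export
qc_filter <- function(coverage, threshold = 0.90) {
  out <- dplyr::mutate(coverage,
                       retained = .data$covered_fraction >= threshold)
  none <- dplyr::summarise(dplyr::group_by(out, .data$compartment),
                           any_kept = any(.data$retained), .groups = "drop")
  if (any(!none$any_kept)) {
    stop("qc_filter removed every sample for compartment(s) ",
         paste(none$compartment[!none$any_kept], collapse = ", "),
         "; review the coverage threshold (", threshold, ")")
  }
  out
}

#' Write per-gene multi-FASTA files of representative sequences
#'
#' One file per gene named `<gene_id>.fasta`, records named by sample.
#'
#' @param representatives tibble from [call_representatives()].
#' @param dir output directory.
#' @return invisible character vector of file paths.
#' @export
write_representatives <- function(representatives, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(representatives, representatives$gene_id),
                  function(d) {
                    p <- file.path(dir, paste0(d$gene_id[1], ".fasta"))
                    write_fasta(tibble::tibble(id = d$sample_id,
                                               sequence = d$sequence), p)
                    p
                  }, character(1))
  invisible(unname(paths))
}
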