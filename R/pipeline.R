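#' Run the full organelle-variation analysis on a cohort
#'
#' Maps every sample's reads to the reference genes, builds pileups, calls
#' representative sequences, applies the per-compartment low-coverage QC
#' filter, detects SNP sites among retained samples, annotates them with the
#' RNA-editing catalogue, classifies them ns/ss, and assembles the variation
#' report.
#'
#' @param cohort an `sv_cohort` from [synthesize_cohort()], or a list with
#'   elements `references`, `catalogue`, `samples`, `reads` in the same
#'   layout.
#' @param k k-mer size of the mapper index.
#' @param max_mismatch_rate mapper mismatch tolerance per base.
#' @param min_depth minimum depth for a consensus call.
#' @param qc_threshold minimum compartment-wide covered fraction to retain a
#'   sample.
#' @param keep_pileups keep the per-sample pileup matrices in the result
#'   (default `TRUE`; set `FALSE` to save memory).
#' @return list of class `sv_analysis` with elements `coverage`, `qc`,
#'   `representatives` (all samples), `retained` (QC-passing representative
#'   sequences, per compartment), `snps`, `gene_stats`, `report`, and
#'   optionally `pileups`.
#' @export
analyze_cohort <- function(cohort, k = 21L, max_mismatch_rate = 0.04,
                           min_depth = 1L, qc_threshold = 0.90,
                           keep_pileups = TRUE) {
  references <- cohort$references
  index <- build_index(references, k)
  ids <- cohort$samples$sample_id
  pileups <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- cohort$reads[cohort$reads$sample_id == ids[i],
                      c("read_id", "sequence")]
    pileups[[i]] <- pileup_sample(d, index, references, sample_id = ids[i],
                                  max_mismatch_rate = max_mismatch_rate)
    attr(pileups[[i]], "placements") <- NULL
  }
  pileups <- dplyr::bind_rows(pileups)
  coverage <- compartment_coverage(pileups, references)
  qc <- qc_filter(coverage, qc_threshold)
  representatives <- call_representatives(pileups, references, min_depth)
  comp <- stats::setNames(references$compartment, references$gene_id)
  retained_key <- paste(qc$sample_id[qc$retained],
                        qc$compartment[qc$retained])
  retained <- representatives[
    paste(representatives$sample_id,
          comp[representatives$gene_id]) %in% retained_key, ]
  snps <- detect_snp_sites(retained)
  snps <- correspond_with_editing(snps, cohort$catalogue)
  snps <- classify_ns_ss(snps, retained, references)
  gene_stats <- summarize_variation(snps, references, cohort$catalogue)
  report <- build_variation_report(gene_stats)
  out <- list(coverage = coverage, qc = qc,
              representatives = representatives, retained = retained,
              snps = snps, gene_stats = gene_stats, report = report)
  if (keep_pileups) out$pileups <- pileups
  structure(out, class = "sv_analysis")
}

#' Population-structure analysis of one compartment
#'
#' Concatenates the QC-retained representative sequences of a compartment,
#' builds the bootstrapped NJ tree and assesses locality-group clustering.
#'
#' @param analysis an `sv_analysis` from [analyze_cohort()].
#' @param references tibble from [reference_genes()].
#' @param metadata tibble with `sample_id`, `locality_group`.
#' @param compartment `"mt"` or `"pt"`.
#' @param n_replicates bootstrap replicates (default 100).
#' @param min_support support threshold for cluster reading (default 70).
#' @param seed optional seed for the bootstrap resampling.
#' @return list with `concatenated`, `boot` (see [bootstrap_support()]) and
#'   `clusters` (see [assess_clusters()]).
#' @export
popstruct_compartment <- function(analysis, references, metadata,
                                  compartment = c("mt", "pt"),
                                  n_replicates = 100L, min_support = 70L,
                                  seed = NULL) {
  compartment <- match.arg(compartment)
  genes <- references$gene_id[references$compartment == compartment]
  reps <- analysis$retained[analysis$retained$gene_id %in% genes, ]
  concatenated <- concatenate_representatives(reps, genes)
  boot <- bootstrap_support(concatenated, n_replicates, seed = seed)
  clusters <- assess_clusters(boot, metadata, min_support)
  list(concatenated = concatenated, boot = boot, clusters = clusters)
}

#' @export
print.sv_analysis <- function(x, ...) {
  cat("<sv_analysis>\n")
  cat("  samples: ", length(unique(x$representatives$sample_id)),
      " (retained per compartment: ",
      paste(sprintf("%s=%d", unique(x$qc$compartment),
                    vapply(unique(x$qc$compartment), function(cc)
                      sum(x$qc$retained[x$qc$compartment == cc]), 0L)),
            collapse = ", "), ")\n", sep = "")
  cat("  SNP sites: ", nrow(x$snps), "\n", sep = "")
  cat("  report rows: ", nrow(x$report), "\n", sep = "")
  invisible(x)
}

#' Published per-gene variation counts of the reference organelle study
#'
#' Per-gene analyzed-site, SNP, possible-RNA-editing and correspondence
#' counts for the 15 Breviolum-referenced organelle genes, as printed in the
#' study this package's default cohort emulates. Shipped as plain TSV in
#' `extdata`; useful as input to [build_variation_report()] and as the
#' calibration source of the generator defaults.
#'
#' @return tibble with columns `gene`, `compartment`, `analyzed_sites`,
#'   `n_snp`, `n_prnae`, `n_correspondence`.
#' @export
published_gene_counts <- function() {
  path <- system.file("extdata", "published_gene_counts.tsv",
                      package = "symbiovar", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
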