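#' Detect SNP sites across a set of representative sequences
#'
#' A site is a SNP iff at least two distinct bases from `A/C/G/T` occur among
#' the samples at that site. `N` is missing data: it never creates a SNP, and
#' a site varying only by `N` is not a SNP. All sequences of a gene must share
#' the reference length (they are aligned by construction, sharing the
#' reference coordinate system).
#'
#' @param representatives tibble with columns `gene_id`, `sample_id`,
#'   `sequence` (typically [call_representatives()] output restricted to
#'   QC-retained samples).
#' @return tibble with one row per SNP site: `gene_id`, `position` (0-based),
#'   `alleles` (list of character vectors), `allele_counts` (list of named
#'   integer vectors), `n_called` (samples with a non-N base), and
#'   `major_allele` (most frequent base, ties to the lexicographically
#'   smallest).
#' @export
detect_snp_sites <- function(representatives) {
  rows <- lapply(split(representatives, representatives$gene_id), function(d) {
    lens <- unique(nchar(d$sequence))
    if (length(lens) != 1) {
      stop("gene ", d$gene_id[1], ": sequences have differing lengths (",
           paste(lens, collapse = ", "), ")")
    }
    m <- seq_char_matrix(d$sequence, d$sample_id)
    cnt <- vapply(DNA_BASES, function(b) colSums(m == b),
                  numeric(ncol(m)))          # sites x 4
    if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1,
                                     dimnames = list(NULL, DNA_BASES))
    n_distinct <- rowSums(cnt > 0)
    snp <- which(n_distinct >= 2)
    if (length(snp) == 0) {
      return(tibble::tibble(gene_id = character(0), position = integer(0),
                            alleles = list(), allele_counts = list(),
                            n_called = integer(0),
                            major_allele = character(0)))
    }
    tibble::tibble(
      gene_id = d$gene_id[1],
      position = snp - 1L,
      alleles = lapply(snp, function(i) DNA_BASES[cnt[i, ] > 0]),
      allele_counts = lapply(snp, function(i) {
        v <- cnt[i, ]; as.integer(v[v > 0]) |>
          stats::setNames(DNA_BASES[v > 0])
      }),
      n_called = as.integer(rowSums(cnt)[snp]),
      major_allele = DNA_BASES[max.col(cnt, ties.method = "first")[snp]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Annotate SNP sites with RNA-editing correspondence
#'
#' A SNP site corresponds to a possible RNA-editing (pRNAe) site when the same
#' (gene, position) pair appears in the editing catalogue.
#' `contains_pre_and_post_edit` records whether both the catalogue's genomic
#' and edited base are among the observed alleles (the gain/loss-of-editing
#' signature); it is `NA` for SNPs outside the catalogue.
#'
#' @param snps tibble from [detect_snp_sites()].
#' @param catalogue editing catalogue tibble (0-based positions).
#' @return `snps` with logical columns `is_prnae` and
#'   `contains_pre_and_post_edit` added.
#' @export
correspond_with_editing <- function(snps, catalogue) {
  key_s <- paste(snps$gene_id, snps$position)
  key_c <- paste(catalogue$gene_id, catalogue$position)
  idx <- match(key_s, key_c)
  snps$is_prnae <- !is.na(idx)
  snps$contains_pre_and_post_edit <- NA
  hit <- which(snps$is_prnae)
  snps$contains_pre_and_post_edit[hit] <- vapply(hit, function(i) {
    j <- idx[i]
    all(c(catalogue$genomic_base[j], catalogue$edited_base[j]) %in%
          snps$alleles[[i]])
  }, logical(1))
  snps
}

#' Classify SNP sites as nonsynonymous or synonymous
#'
#' The codon holding each SNP site is built with the cohort consensus-major
#' base at the other two codon positions. Every alternate allele at the site
#' is substituted in turn; if any substitution changes the encoded amino acid
#' relative to the major-allele codon, the site is nonsynonymous (`ns`), else
#' synonymous (`ss`) — a codon site showing both kinds counts as `ns`. Sites
#' falling in a trailing partial codon are excluded with a warning
#' (`class = NA`).
#'
#' @param snps tibble from [detect_snp_sites()] (optionally annotated).
#' @param representatives the representative sequences used for SNP detection
#'   (needed for the per-site consensus-major background).
#' @param references tibble from [reference_genes()]; genes must be complete
#'   CDS in frame.
#' @return `snps` with a `class` column (`"ns"`, `"ss"`, or `NA` for excluded
#'   sites).
#' @export
classify_ns_ss <- function(snps, representatives, references) {
  snps$class <- NA_character_
  for (g in unique(snps$gene_id)) {
    ref <- ref_row(references, g)
    code <- Biostrings::getGeneticCode(as.character(ref$translation_table_id))
    d <- representatives[representatives$gene_id == g, ]
    m <- seq_char_matrix(d$sequence, d$sample_id)
    cnt <- vapply(DNA_BASES, function(b) colSums(m == b), numeric(ncol(m)))
    if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1,
                                     dimnames = list(NULL, DNA_BASES))
    major <- DNA_BASES[max.col(cnt, ties.method = "first")]
    refc <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
    major[rowSums(cnt) == 0] <- refc[rowSums(cnt) == 0]
    # prefer the reference base on count ties, mirroring consensus calling
    ref_idx <- match(refc, DNA_BASES)
    mx <- apply(cnt, 1, max)
    tie_ref <- cnt[cbind(seq_along(refc), ref_idx)] == mx & mx > 0
    major[tie_ref] <- refc[tie_ref]

    idx <- which(snps$gene_id == g)
    for (i in idx) {
      pos <- snps$position[i]                      # 0-based
      codon_i <- (pos - ref$frame_offset) %/% 3L
      c0 <- ref$frame_offset + 3L * codon_i        # codon start, 0-based
      if (codon_i < 0L || c0 + 2L >= ref$length) {
        warning("gene ", g, " position ", pos + 1L,
                " falls outside a complete codon; excluded from ns/ss")
        next
      }
      codon <- major[(c0 + 1L):(c0 + 3L)]
      within <- pos - c0 + 1L
      site_major <- snps$major_allele[i]
      codon[within] <- site_major
      aa_major <- code[[paste0(codon, collapse = "")]]
      alts <- setdiff(snps$alleles[[i]], site_major)
      any_ns <- FALSE
      for (a in alts) {
        alt_codon <- codon
        alt_codon[within] <- a
        if (code[[paste0(alt_codon, collapse = "")]] != aa_major) {
          any_ns <- TRUE
          break
        }
      }
      snps$class[i] <- if (any_ns) "ns" else "ss"
    }
  }
  snps
}

#' Summarise per-gene variation statistics from annotated SNP sites
#'
#' @param snps tibble from [classify_ns_ss()] (with `is_prnae` and `class`).
#' @param references tibble from [reference_genes()] (defines analyzed sites
#'   = gene length, and the gene order of the report).
#' @param catalogue editing catalogue tibble (defines `n_prnae` per gene).
#' @return per-gene statistics tibble suitable for
#'   [build_variation_report()].
#' @export
summarize_variation <- function(snps, references, catalogue) {
  per_gene <- lapply(seq_len(nrow(references)), function(i) {
    g <- references$gene_id[i]
    s <- snps[snps$gene_id == g, ]
    tibble::tibble(
      gene = g,
      compartment = references$compartment[i],
      analyzed_sites = references$length[i],
      n_snp = nrow(s),
      n_prnae = sum(catalogue$gene_id == g),
      n_correspondence = sum(s$is_prnae),
      n_ns = sum(s$class == "ns", na.rm = TRUE),
      n_ss = sum(s$class == "ss", na.rm = TRUE)
    )
  })
  dplyr::bind_rows(per_gene)
}

#' Build the variation report (per-gene rows plus compartment totals)
#'
#' Percentages are computed from the integer columns and rounded half-up to
#' one decimal, the display convention of the per-gene summary table:
#' `snp_pct = 100 * n_snp / analyzed_sites`, `prnae_pct` likewise, and the
#' correspondence shares `corr_per_snp_pct` (of SNP sites) and
#' `corr_per_prnae_pct` (of pRNAe sites). A `TOTAL` row is appended per
#' compartment.
#'
#' @param gene_stats tibble with columns `gene`, `compartment`,
#'   `analyzed_sites`, `n_snp`, `n_prnae`, `n_correspondence` and optionally
#'   `n_ns`, `n_ss` (as from [summarize_variation()], or published per-gene
#'   counts).
#' @return tibble of class `sv_report`.
#' @export
build_variation_report <- function(gene_stats) {
  if (!"n_ns" %in% names(gene_stats)) gene_stats$n_ns <- NA_integer_
  if (!"n_ss" %in% names(gene_stats)) gene_stats$n_ss <- NA_integer_
  gene_stats$is_total <- FALSE
  totals <- dplyr::summarise(
    dplyr::group_by(gene_stats, .data$compartment),
    gene = "TOTAL",
    analyzed_sites = sum(.data$analyzed_sites),
    n_snp = sum(.data$n_snp),
    n_prnae = sum(.data$n_prnae),
    n_correspondence = sum(.data$n_correspondence),
    n_ns = if (all(is.na(.data$n_ns))) NA_integer_ else
      sum(.data$n_ns, na.rm = TRUE),
    n_ss = if (all(is.na(.data$n_ss))) NA_integer_ else
      sum(.data$n_ss, na.rm = TRUE),
    is_total = TRUE,
    .groups = "drop"
  )
  out <- dplyr::bind_rows(
    lapply(split(gene_stats, factor(gene_stats$compartment,
                                    levels = unique(gene_stats$compartment))),
           function(d) dplyr::bind_rows(
             d, totals[totals$compartment == d$compartment[1], names(d)]))
  )
  out <- dplyr::mutate(
    out,
    snp_pct = pct1(.data$n_snp, .data$analyzed_sites),
    prnae_pct = pct1(.data$n_prnae, .data$analyzed_sites),
    corr_per_snp_pct = pct1(.data$n_correspondence, .data$n_snp),
    corr_per_prnae_pct = pct1(.data$n_correspondence, .data$n_prnae)
  )
  out <- out[, c("gene", "compartment", "analyzed_sites", "n_snp", "snp_pct",
                 "n_prnae", "prnae_pct", "n_correspondence",
                 "corr_per_snp_pct", "corr_per_prnae_pct",
                 "n_ns", "n_ss", "is_total")]
  class(out) <- c("sv_report", class(out))
  out
}

#' Write a variation report as TSV
#'
#' Columns: `gene`, `compartment`, `analyzed_sites`, `n_snp`, `snp_pct` (one
#' decimal), `n_prnae`, `n_correspondence`, `n_ns`, `n_ss`; one `TOTAL` row
#' per compartment. An empty report writes the header only.
#'
#' @param report tibble from [build_variation_report()] (or zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  cols <- c("gene", "compartment", "analyzed_sites", "n_snp", "snp_pct",
            "n_prnae", "n_correspondence", "n_ns", "n_ss")
  if (nrow(report) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- as.data.frame(report)[, cols]
  out$snp_pct <- sprintf("%.1f", out$snp_pct)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write detected SNP sites as TSV (1-based positions)
#'
#' @param snps annotated SNP tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_sites <- function(snps, path) {
  out <- tibble::tibble(
    gene_id = snps$gene_id,
    position_1based = snps$position + 1L,
    alleles = vapply(snps$alleles, paste, character(1), collapse = "/"),
    allele_counts = vapply(snps$allele_counts, function(v)
      paste0(names(v), "=", v, collapse = ";"), character(1)),
    is_prnae = snps$is_prnae %||% NA,
    contains_pre_and_post_edit = snps$contains_pre_and_post_edit %||% NA,
    class = snps$class %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
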