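#' Default organelle gene set
#'
#' The 3 mitochondrial (cox1, cox3, cob) and 12 plastid minicircle genes with
#' the coding-sequence lengths used throughout the package: 3,288 mt sites and
#' 13,959 pt sites in total.
#'
#' @return tibble with columns `gene_id`, `compartment`, `length`.
#' @export
default_gene_table <- function() {
  tibble::tibble(
    gene_id = c("cox1", "cox3", "cob",
                "psbA", "psbB", "psbC", "psbD", "psbE", "psbI",
                "petB", "petD", "psaA", "psaB", "atpA", "atpB"),
    compartment = c(rep("mt", 3), rep("pt", 12)),
    length = c(1455L, 771L, 1062L,
               1029L, 1500L, 1359L, 1074L, 234L, 108L,
               657L, 477L, 2022L, 2094L, 1434L, 1971L)
  )
}

#' Configuration of a synthetic holobiont cohort
#'
#' Defaults describe the study conditions the analysis is designed for: 155
#' samples across four locality groups (Okinawa `OK`, Kerama `KR`,
#' Yaeyama-North `YN`, Yaeyama-South `YS`), the 15 organelle genes of
#' [default_gene_table()], ~35x mitochondrial and ~9x plastid read coverage
#' with 100 bp paired-end reads, editing-site densities of 72/3,288 (mt) and
#' 406/13,959 (pt), and per-compartment probabilities that a site is
#' polymorphic given it is / is not an editing site (mt 68/72 and
#' 117/3,216; pt 81/406 and 1,179/13,553). Five samples are coverage-starved
#' to exercise the per-compartment QC rule. One locality group (default
#' `YN`) carries a diverged haplotype pool so that population structure is
#' recoverable by the tree stage.
#'
#' @param n_samples_per_group named integer vector over OK/KR/YN/YS.
#' @param genes tibble with `gene_id`, `compartment`, `length` columns.
#' @param mt_coverage,pt_coverage target mean read depth per compartment.
#' @param read_length read length in bp, 75..100.
#' @param error_rate per-base substitution error probability.
#' @param editing_site_density named per-compartment fraction of sites in the
#'   editing catalogue.
#' @param p_snp_at_editing_site,p_snp_at_nonediting_site named per-compartment
#'   probabilities that a site is polymorphic.
#' @param maf_shape Beta shape parameters of the minor-allele-frequency
#'   spectrum of shared polymorphic sites (skewed toward rare variants, as in
#'   a neutral site-frequency spectrum).
#' @param maf_range clamp bounds applied to the drawn frequency.
#' @param diverged_group locality group drawn from a diverged haplotype pool
#'   (`NULL` for none).
#' @param p_discriminating fraction of polymorphic sites that discriminate the
#'   diverged group from the rest.
#' @param diverged_freq_in,diverged_freq_out alternate-allele frequency at
#'   discriminating sites inside/outside the diverged group.
#' @param n_low_coverage_samples number of samples whose coverage is starved
#'   (multiplied by `low_coverage_factor`).
#' @param low_coverage_factor multiplier applied to starved samples; the
#'   default 0.02 leaves the residual coverage far enough below the QC
#'   boundary that the low-coverage rule triggers for every seed.
#' @param n_its2_typed_samples number of samples given typable ITS2 reads.
#' @param its2_reads_range inclusive range of ITS2 reads per typed sample.
#' @param its2_types ITS2 type labels; labels starting with `"D"` are planted
#'   only in Yaeyama (YN/YS) samples.
#' @param its2_ref_length,its2_type_divergence length of each ITS2 reference
#'   and pairwise divergence between types.
#' @param seed integer seed controlling every random draw of the generator.
#' @return a list of class `sv_config`.
#' @export
cohort_config <- function(
    n_samples_per_group = c(OK = 60L, KR = 35L, YN = 30L, YS = 30L),
    genes = default_gene_table(),
    mt_coverage = 35,
    pt_coverage = 9,
    read_length = 100L,
    error_rate = 0.001,
    editing_site_density = c(mt = 72 / 3288, pt = 406 / 13959),
    p_snp_at_editing_site = c(mt = 68 / 72, pt = 81 / 406),
    p_snp_at_nonediting_site = c(mt = 117 / 3216, pt = 1179 / 13553),
    maf_shape = c(0.8, 4),
    maf_range = c(0.02, 0.5),
    diverged_group = "YN",
    p_discriminating = 0.15,
    diverged_freq_in = 0.95,
    diverged_freq_out = 0.02,
    n_low_coverage_samples = 5L,
    low_coverage_factor = 0.02,
    n_its2_typed_samples = 51L,
    its2_reads_range = c(2L, 8L),
    its2_types = c("C1", "C3", "C15", "D1"),
    its2_ref_length = 320L,
    its2_type_divergence = 0.08,
    seed = 1L) {
  cfg <- list(
    n_samples_per_group = n_samples_per_group,
    genes = genes,
    mt_coverage = mt_coverage, pt_coverage = pt_coverage,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    editing_site_density = editing_site_density,
    p_snp_at_editing_site = p_snp_at_editing_site,
    p_snp_at_nonediting_site = p_snp_at_nonediting_site,
    maf_shape = maf_shape,
    maf_range = maf_range,
    diverged_group = diverged_group,
    p_discriminating = p_discriminating,
    diverged_freq_in = diverged_freq_in,
    diverged_freq_out = diverged_freq_out,
    n_low_coverage_samples = as.integer(n_low_coverage_samples),
    low_coverage_factor = low_coverage_factor,
    n_its2_typed_samples = as.integer(n_its2_typed_samples),
    its2_reads_range = as.integer(its2_reads_range),
    its2_types = its2_types,
    its2_ref_length = as.integer(its2_ref_length),
    its2_type_divergence = its2_type_divergence,
    seed = as.integer(seed)
  )
  probs <- c(cfg$editing_site_density, cfg$p_snp_at_editing_site,
             cfg$p_snp_at_nonediting_site,
             cfg$p_discriminating, cfg$diverged_freq_in,
             cfg$diverged_freq_out, cfg$maf_range, cfg$error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and densities must lie in [0, 1]")
  }
  if (cfg$mt_coverage <= 0 || cfg$pt_coverage <= 0) {
    stop("coverages must be positive")
  }
  if (cfg$read_length < 75L || cfg$read_length > 100L) {
    stop("read_length must lie in [75, 100]")
  }
  if (any(cfg$genes$length < 3L) || any(cfg$genes$length %% 3L != 0L)) {
    stop("gene lengths must be >= 3 and divisible by 3")
  }
  if (!all(names(cfg$n_samples_per_group) %in% c("OK", "KR", "YN", "YS"))) {
    stop("locality groups must be among OK, KR, YN, YS")
  }
  if (cfg$n_low_coverage_samples >= sum(cfg$n_samples_per_group)) {
    stop("cannot starve every sample in the cohort")
  }
  structure(cfg, class = "sv_config")
}

#' @keywords internal
compartment_of <- function(config) {
  stats::setNames(config$genes$compartment, config$genes$gene_id)
}
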