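#' Tidy a variation report: per-gene rows
#'
#' @param x an `sv_report`.
#' @param ... unused.
#' @return tibble of the per-gene rows (TOTAL rows dropped).
#' @export
tidy.sv_report <- function(x, ...) {
  out <- tibble::as_tibble(x[!x$is_total, setdiff(names(x), "is_total")])
  out
}

#' Glance at a variation report: one row per compartment
#'
#' @param x an `sv_report`.
#' @param ... unused.
#' @return tibble with compartment totals and correspondence shares.
#' @export
glance.sv_report <- function(x, ...) {
  tibble::as_tibble(x[x$is_total, setdiff(names(x), c("gene", "is_total"))])
}

#' @export
tidy.sv_clusters <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "clade_samples")])
}

#' @export
tidy.sv_its2 <- function(x, ...) x$assignments

#' @export
glance.sv_its2 <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$assignments),
    n_assigned = sum(x$assignments$assigned),
    n_types = length(unique(stats::na.omit(x$assignments$best_type))),
    n_typed_samples = count_typed_samples(x)
  )
}

#' @export
glance.sv_analysis <- function(x, ...) glance(x$report)

#' @export
tidy.sv_analysis <- function(x, ...) tidy(x$report)

#' Plot per-gene SNP and editing-site percentages
#'
#' Side-by-side bars of the SNP and possible-RNA-editing percentages per
#' gene, faceted by genome compartment.
#'
#' @param object an `sv_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sv_report <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(
    d[, c("gene", "compartment", "snp_pct", "prnae_pct")],
    cols = c("snp_pct", "prnae_pct"),
    names_to = "metric", values_to = "pct")
  d$metric <- factor(d$metric, levels = c("snp_pct", "prnae_pct"),
                     labels = c("SNP sites", "possible RNA-editing sites"))
  d$gene <- factor(d$gene, levels = unique(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$pct,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(~ .data$compartment, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "% of analyzed sites", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot SNP/editing correspondence shares per compartment
#'
#' Shows the correspondence count as a share of SNP sites and as a share of
#' editing-catalogue sites, per compartment.
#'
#' @param report an `sv_report`.
#' @return a ggplot object.
#' @export
plot_correspondence <- function(report) {
  d <- glance(report)
  d <- tidyr::pivot_longer(
    d[, c("compartment", "corr_per_snp_pct", "corr_per_prnae_pct")],
    cols = -"compartment", names_to = "share", values_to = "pct")
  d$share <- factor(d$share,
                    levels = c("corr_per_snp_pct", "corr_per_prnae_pct"),
                    labels = c("of SNP sites", "of pRNAe sites"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$pct,
                                  fill = .data$share)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "compartment", y = "correspondence (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot locality-group cluster sizes
#'
#' @param object an `sv_clusters` tibble from [assess_clusters()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sv_clusters <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locality_group,
                                  y = .data$clade_size)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$clade_support)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_samples_in_tree),
                        shape = 95, size = 8) +
    ggplot2::labs(x = "locality group",
                  y = "largest exclusive supported clade (dash: group size)",
                  fill = "support (%)") +
    ggplot2::theme_minimal()
}
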