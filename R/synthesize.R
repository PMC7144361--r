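#' Generate random reference organelle genes
#'
#' Produces one uniformly random CDS per configured gene (frame offset 0,
#' standard translation table), with exactly the configured lengths.
#'
#' @param config an `sv_config` from [cohort_config()].
#' @return tibble from [reference_genes()].
#' @export
generate_references <- function(config) {
  reference_genes(gene_id = config$genes$gene_id,
                  compartment = config$genes$compartment,
                  sequence = random_dna(config$genes$length))
}

#' Generate an RNA-editing site catalogue for synthetic references
#'
#' Per gene, the number of edited sites is binomial in the gene length at the
#' compartment's editing-site density; positions are drawn without
#' replacement and each edited base differs from the genomic base.
#'
#' @param references tibble from [reference_genes()].
#' @param config an `sv_config`.
#' @return catalogue tibble (`gene_id`, 0-based `position`, `genomic_base`,
#'   `edited_base`).
#' @export
generate_editing_catalogue <- function(references, config) {
  rows <- lapply(seq_len(nrow(references)), function(i) {
    L <- references$length[i]
    dens <- config$editing_site_density[[references$compartment[i]]]
    n <- stats::rbinom(1, L, dens)
    if (n == 0) {
      return(tibble::tibble(gene_id = character(0), position = integer(0),
                            genomic_base = character(0),
                            edited_base = character(0)))
    }
    if (n > L) stop("editing-site density too high for gene ",
                    references$gene_id[i])
    pos <- sort(sample.int(L, n)) - 1L
    gbase <- substring(references$sequence[i], pos + 1L, pos + 1L)
    ebase <- vapply(gbase, function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
    tibble::tibble(gene_id = references$gene_id[i], position = pos,
                   genomic_base = gbase, edited_base = ebase)
  })
  dplyr::bind_rows(rows)
}

#' Build the sample metadata table of a cohort
#' @keywords internal
generate_samples <- function(config) {
  groups <- rep(names(config$n_samples_per_group),
                config$n_samples_per_group)
  ids <- unlist(lapply(names(config$n_samples_per_group), function(g) {
    sprintf("%s%02d", g, seq_len(config$n_samples_per_group[[g]]))
  }))
  low <- rep(FALSE, length(ids))
  if (config$n_low_coverage_samples > 0) {
    low[sample.int(length(ids), config$n_low_coverage_samples)] <- TRUE
  }
  tibble::tibble(sample_id = ids, locality_group = groups,
                 low_coverage = low)
}

#' Generate per-sample population haplotypes and the ground-truth SNP table
#'
#' Each site becomes polymorphic independently with the compartment's
#' `p_snp_at_editing_site` if it is in the catalogue, else
#' `p_snp_at_nonediting_site`. At a polymorphic editing site the two alleles
#' are the genomic and the edited base (so a gain/loss of editing shows up as
#' the pre-/post-edit base pair); elsewhere the alternate is a random other
#' base. A configurable fraction of polymorphic sites discriminates the
#' diverged locality group (alternate allele near-fixed inside it, near-absent
#' outside), which is what makes that group separable by the tree stage; the
#' remaining sites share one cohort-wide minor-allele frequency drawn from a
#' Beta spectrum skewed toward rare variants. Every
#' polymorphic site is forced to segregate in at least two samples per
#' allele.
#'
#' @param references tibble from [reference_genes()].
#' @param catalogue editing catalogue tibble.
#' @param samples sample metadata tibble (`sample_id`, `locality_group`).
#' @param config an `sv_config`.
#' @return list with `haplotypes` (tibble `sample_id`, `gene_id`,
#'   `sequence`) and `truth` (tibble `gene_id`, `position`, `ref_allele`,
#'   `alt_allele`, `is_editing_site`, `discriminating`, `n_alt`,
#'   `alt_samples` list-column).
#' @export
generate_haplotypes <- function(references, catalogue, samples, config) {
  ns <- nrow(samples)
  in_div <- !is.null(config$diverged_group) &&
    length(config$diverged_group) > 0
  div_mask <- if (in_div) samples$locality_group %in% config$diverged_group
              else rep(FALSE, ns)
  hap_rows <- vector("list", nrow(references))
  truth_rows <- vector("list", nrow(references))
  for (i in seq_len(nrow(references))) {
    g <- references$gene_id[i]
    L <- references$length[i]
    comp <- references$compartment[i]
    refc <- strsplit(references$sequence[i], "", fixed = TRUE)[[1]]
    cat_g <- catalogue[catalogue$gene_id == g, ]
    is_edit <- logical(L)
    is_edit[cat_g$position + 1L] <- TRUE
    p_site <- ifelse(is_edit,
                     config$p_snp_at_editing_site[[comp]],
                     config$p_snp_at_nonediting_site[[comp]])
    pol <- which(stats::runif(L) < p_site)
    alt <- character(length(pol))
    if (length(pol)) {
      edited_at <- stats::setNames(cat_g$edited_base, cat_g$position + 1L)
      for (j in seq_along(pol)) {
        p <- pol[j]
        alt[j] <- if (is_edit[p]) edited_at[[as.character(p)]] else
          sample(setdiff(DNA_BASES, refc[p]), 1)
      }
    }
    disc <- stats::runif(length(pol)) < (if (in_div) config$p_discriminating else 0)
    mat <- matrix(rep(refc, each = ns), nrow = ns)
    alt_samples <- vector("list", length(pol))
    n_alt <- integer(length(pol))
    for (j in seq_along(pol)) {
      if (disc[j]) {
        freq <- ifelse(div_mask, config$diverged_freq_in,
                       config$diverged_freq_out)
      } else {
        f <- stats::rbeta(1, config$maf_shape[1], config$maf_shape[2])
        freq <- rep(min(max(f, config$maf_range[1]), config$maf_range[2]),
                    ns)
      }
      carrier <- stats::runif(ns) < freq
      # force both alleles to segregate in >= 2 samples (cohorts of >= 4)
      if (ns >= 4L) {
        if (sum(carrier) < 2L) {
          carrier[sample.int(ns, 2L)] <- TRUE
        }
        if (sum(!carrier) < 2L) {
          carrier[sample.int(ns, 2L)] <- FALSE
        }
      }
      mat[carrier, pol[j]] <- alt[j]
      alt_samples[[j]] <- samples$sample_id[carrier]
      n_alt[j] <- sum(carrier)
    }
    seqs <- apply(mat, 1L, paste0, collapse = "")
    hap_rows[[i]] <- tibble::tibble(sample_id = samples$sample_id,
                                    gene_id = g, sequence = seqs)
    truth_rows[[i]] <- tibble::tibble(
      gene_id = g, position = pol - 1L,
      ref_allele = refc[pol], alt_allele = alt,
      is_editing_site = is_edit[pol], discriminating = disc,
      n_alt = n_alt, alt_samples = alt_samples
    )
  }
  list(haplotypes = dplyr::bind_rows(hap_rows),
       truth = dplyr::bind_rows(truth_rows))
}

#' Simulate paired-end reads for every sample
#'
#' Fragments of fixed length `2 * read_length + 50` are placed uniformly,
#' allowed to overhang the gene ends (reads are clipped to the gene, mimicking
#' reads that extend into flanking genomic context), which keeps realized
#' depth uniform across the CDS. Mates are written forward/reverse;
#' substitution errors are injected per base at `error_rate`. Clipped reads
#' shorter than 30 bp are dropped. Coverage-starved samples get
#' `low_coverage_factor` times the target number of fragments.
#'
#' @param haplotypes tibble from [generate_haplotypes()].
#' @param samples sample metadata tibble with `low_coverage` column.
#' @param references tibble from [reference_genes()].
#' @param config an `sv_config`.
#' @return tibble with columns `sample_id`, `gene_id` (true origin),
#'   `read_id`, `mate`, `sequence`.
#' @export
simulate_reads <- function(haplotypes, samples, references, config) {
  rl <- config$read_length
  frag <- 2L * rl + 50L
  min_len <- 30L
  comp <- stats::setNames(references$compartment, references$gene_id)
  cov0 <- c(mt = config$mt_coverage, pt = config$pt_coverage)
  out <- vector("list", nrow(haplotypes))
  for (r in seq_len(nrow(haplotypes))) {
    sid <- haplotypes$sample_id[r]
    g <- haplotypes$gene_id[r]
    hap <- haplotypes$sequence[r]
    L <- nchar(hap)
    cc <- cov0[[comp[[g]]]]
    if (samples$low_coverage[match(sid, samples$sample_id)]) {
      cc <- cc * config$low_coverage_factor
    }
    n_pairs <- max(0L, as.integer(round(cc * (L + frag - 1) / (2 * rl))))
    if (n_pairs == 0L) { out[[r]] <- NULL; next }
    s <- sample.int(L + frag - 1L, n_pairs, replace = TRUE) - frag  # 0-based
    a1 <- pmax(s, 0L); b1 <- pmin(s + rl - 1L, L - 1L)
    a2 <- pmax(s + frag - rl, 0L); b2 <- pmin(s + frag - 1L, L - 1L)
    r1 <- substring(hap, a1 + 1L, b1 + 1L)
    r2 <- revcomp(substring(hap, a2 + 1L, b2 + 1L))
    ids <- sprintf("%s:%s:%d", sid, g, seq_len(n_pairs))
    d <- tibble::tibble(
      sample_id = sid, gene_id = g,
      read_id = c(ids, ids),
      mate = rep(c(1L, 2L), each = n_pairs),
      sequence = c(r1, r2)
    )
    d <- d[nchar(d$sequence) >= min_len, ]
    if (config$error_rate > 0 && nrow(d) > 0) {
      d$sequence <- inject_errors(d$sequence, config$error_rate)
    }
    out[[r]] <- d
  }
  dplyr::bind_rows(out)
}

#' Substitute random bases at a per-base error rate
#' @keywords internal
inject_errors <- function(seqs, error_rate) {
  nerr <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), nerr[i])
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
    seqs[i] <- paste0(ch, collapse = "")
  }
  seqs
}

#' Generate ITS2 reference sequences for the configured types
#'
#' One random ancestral sequence is mutated independently per type at the
#' configured divergence, so types are distinguishable by alignment score.
#'
#' @param config an `sv_config`.
#' @return tibble with columns `type`, `ref_id`, `sequence`.
#' @export
generate_its2_references <- function(config) {
  base <- strsplit(random_dna(config$its2_ref_length), "", fixed = TRUE)[[1]]
  L <- length(base)
  n_mut <- max(1L, as.integer(round(config$its2_type_divergence * L)))
  seqs <- vapply(config$its2_types, function(t) {
    ch <- base
    pos <- sample.int(L, n_mut)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
    paste0(ch, collapse = "")
  }, character(1))
  tibble::tibble(type = config$its2_types,
                 ref_id = paste0(config$its2_types, "|ref1"),
                 sequence = unname(seqs))
}

#' Plant ITS2 reads in a subset of samples
#'
#' `n_its2_typed_samples` samples receive between `its2_reads_range[1]` and
#' `its2_reads_range[2]` reads drawn from one ITS2 type each; types whose
#' label starts with `"D"` (Durusdinium-like) are planted only in Yaeyama
#' (YN/YS) samples. Reads are random substrings of the type reference at the
#' configured read length, on a random strand, with substitution errors.
#'
#' @param samples sample metadata tibble.
#' @param its2_refs tibble from [generate_its2_references()].
#' @param config an `sv_config`.
#' @return list with `reads` (tibble `sample_id`, `read_id`, `sequence`) and
#'   `truth` (tibble `sample_id`, `type`, `n_reads`).
#' @export
generate_its2_reads <- function(samples, its2_refs, config) {
  n_typed <- min(config$n_its2_typed_samples, nrow(samples))
  typed <- sort(sample.int(nrow(samples), n_typed))
  d_types <- config$its2_types[startsWith(config$its2_types, "D")]
  c_types <- setdiff(config$its2_types, d_types)
  rl <- min(config$read_length, config$its2_ref_length)
  reads <- vector("list", n_typed)
  truth <- vector("list", n_typed)
  for (i in seq_along(typed)) {
    sid <- samples$sample_id[typed[i]]
    yaeyama <- samples$locality_group[typed[i]] %in% c("YN", "YS")
    pool <- if (yaeyama && length(d_types) > 0 && stats::runif(1) < 0.5)
      d_types else c_types
    type <- sample(pool, 1)
    refseq <- its2_refs$sequence[match(type, its2_refs$type)]
    n_reads <- sample(seq(config$its2_reads_range[1],
                          config$its2_reads_range[2]), 1)
    starts <- sample.int(nchar(refseq) - rl + 1L, n_reads, replace = TRUE)
    seqs <- substring(refseq, starts, starts + rl - 1L)
    flip <- stats::runif(n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    if (config$error_rate > 0) seqs <- inject_errors(seqs, config$error_rate)
    reads[[i]] <- tibble::tibble(
      sample_id = sid,
      read_id = sprintf("%s:its2:%d", sid, seq_len(n_reads)),
      sequence = seqs
    )
    truth[[i]] <- tibble::tibble(sample_id = sid, type = type,
                                 n_reads = n_reads)
  }
  list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
}

#' Generate a complete synthetic holobiont cohort
#'
#' Runs every generator stage under one seed: references, editing catalogue,
#' sample metadata, population haplotypes with truth table, paired-end
#' organelle reads, and ITS2 references/reads. Identical config and seed give
#' byte-identical output.
#'
#' @param config an `sv_config` from [cohort_config()].
#' @return list of class `sv_cohort` with elements `config`, `references`,
#'   `catalogue`, `samples`, `haplotypes`, `truth`, `reads`, `its2_refs`,
#'   `its2_reads`, `its2_truth`.
#' @export
synthesize_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  references <- generate_references(config)
  catalogue <- generate_editing_catalogue(references, config)
  samples <- generate_samples(config)
  hp <- generate_haplotypes(references, catalogue, samples, config)
  reads <- simulate_reads(hp$haplotypes, samples, references, config)
  its2_refs <- generate_its2_references(config)
  its2 <- generate_its2_reads(samples, its2_refs, config)
  structure(
    list(config = config, references = references, catalogue = catalogue,
         samples = samples, haplotypes = hp$haplotypes, truth = hp$truth,
         reads = reads, its2_refs = its2_refs, its2_reads = its2$reads,
         its2_truth = its2$truth),
    class = "sv_cohort"
  )
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Emits `references.fasta`, `editing_sites.tsv`, `samples.tsv`, `truth.tsv`,
#' `its2_references.fasta` (headers `type|id`), per-sample
#' `<sample>_R1.fastq`/`_R2.fastq`, and a flat `config.tsv` of scalar
#' configuration fields.
#'
#' @param cohort an `sv_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dplyr::rename(cohort$references[c("gene_id", "sequence")],
                            id = "gene_id"),
              file.path(dir, "references.fasta"))
  write_editing_catalogue(cohort$catalogue,
                          file.path(dir, "editing_sites.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  truth_flat <- dplyr::mutate(cohort$truth, alt_samples = vapply(
    .data$alt_samples, paste, character(1), collapse = ","))
  readr::write_tsv(truth_flat, file.path(dir, "truth.tsv"))
  write_fasta(tibble::tibble(id = cohort$its2_refs$ref_id,
                             sequence = cohort$its2_refs$sequence),
              file.path(dir, "its2_references.fasta"))
  for (sid in cohort$samples$sample_id) {
    d <- cohort$reads[cohort$reads$sample_id == sid, ]
    write_fastq_pair(d,
                     file.path(dir, paste0(sid, "_R1.fastq")),
                     file.path(dir, paste0(sid, "_R2.fastq")))
  }
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1, cohort$config)
  readr::write_tsv(tibble::tibble(key = names(scalars),
                                  value = vapply(scalars, as.character,
                                                 character(1))),
                   file.path(dir, "config.tsv"))
  invisible(dir)
}
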