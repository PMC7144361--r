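reps_from_columns <- function(cols, gene = "g") {
  # cols: list of per-site character vectors (one element per sample)
  n <- length(cols[[1]])
  seqs <- vapply(seq_len(n), function(i)
    paste0(vapply(cols, `[`, character(1), i), collapse = ""), character(1))
  tibble::tibble(gene_id = gene, sample_id = paste0("s", seq_len(n)),
                 sequence = seqs)
}

test_that("SNP definition ignores N and requires two distinct real bases", {
  reps <- reps_from_columns(list(
    c("A", "A", "A"),   # conserved
    c("A", "G", "N"),   # SNP with alleles {A, G}
    c("A", "N", "N"),   # varies only by N: not a SNP
    c("N", "N", "N"),   # all missing: not a SNP
    c("A", "G", "T")    # multi-allelic: one SNP site
  ))
  snps <- detect_snp_sites(reps)
  expect_equal(snps$position, c(1L, 4L))
  expect_equal(snps$alleles[[1]], c("A", "G"))
  expect_equal(snps$n_called[1], 2L)
  expect_equal(snps$alleles[[2]], c("A", "G", "T"))
  expect_error(
    detect_snp_sites(tibble::tibble(gene_id = "g",
                                    sample_id = c("a", "b"),
                                    sequence = c("AAA", "AAAA"))),
    "differing lengths")
})

test_that("adding a sample never decreases the number of SNP sites", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 8L; L <- 60L
    base <- random_dna_test(L)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- strsplit(base, "", fixed = TRUE)[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        pos <- sample.int(L, k)
        ch[pos] <- sample(c("A", "C", "G", "T", "N"), k, replace = TRUE)
      }
      paste0(ch, collapse = "")
    }, character(1))
    d <- tibble::tibble(gene_id = "g", sample_id = paste0("s", 1:n),
                        sequence = seqs)
    for (m in 2:(n - 1)) {
      expect_lte(nrow(detect_snp_sites(d[1:m, ])),
                 nrow(detect_snp_sites(d[1:(m + 1), ])))
    }
  }
})

test_that("editing correspondence equals brute-force set intersection", {
  set.seed(83)
  L <- 30L
  ref <- reference_genes("g", "mt", random_dna_test(L))
  refc <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  # plant 12 SNP positions and a 10-site catalogue with 7 overlaps
  snp_pos <- sort(sample.int(L, 12L)) - 1L
  cat_pos <- c(sample(snp_pos, 7L), setdiff(0:(L - 1), snp_pos)[1:3])
  catalogue <- tibble::tibble(
    gene_id = "g", position = as.integer(cat_pos),
    genomic_base = refc[cat_pos + 1],
    edited_base = vapply(refc[cat_pos + 1], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1)))
  cols <- lapply(seq_len(L) - 1L, function(p) {
    if (p %in% snp_pos) {
      alt <- if (p %in% cat_pos)
        catalogue$edited_base[match(p, catalogue$position)]
      else setdiff(c("A", "C", "G", "T"), refc[p + 1])[2]
      c(refc[p + 1], alt, refc[p + 1], alt)
    } else rep(refc[p + 1], 4)
  })
  snps <- detect_snp_sites(reps_from_columns(cols))
  ann <- correspond_with_editing(snps, catalogue)
  expect_equal(sum(ann$is_prnae), length(intersect(snp_pos, cat_pos)))
  expect_setequal(ann$position[ann$is_prnae], intersect(snp_pos, cat_pos))
  # pre/post-edit signature: both catalogue bases among observed alleles
  expect_true(all(ann$contains_pre_and_post_edit[ann$is_prnae]))
  expect_true(all(is.na(ann$contains_pre_and_post_edit[!ann$is_prnae])))

  # a SNP whose alleles do not span the edit pair is flagged FALSE
  p0 <- catalogue$position[1]
  third <- setdiff(c("A", "C", "G", "T"),
                   c(catalogue$genomic_base[1], catalogue$edited_base[1]))[1]
  cols[[p0 + 1]] <- c(refc[p0 + 1], third, refc[p0 + 1], third)
  ann2 <- correspond_with_editing(detect_snp_sites(reps_from_columns(cols)),
                                  catalogue)
  expect_false(ann2$contains_pre_and_post_edit[ann2$position == p0])
})

test_that("ns/ss classification follows codon degeneracy and the ns-wins rule", {
  # gene GGA TTA: site 2 (0-based) is 4-fold degenerate third position
  ref <- reference_genes("g", "mt", "GGATTA")
  reps <- reps_from_columns(list(
    c("G", "G", "G"), c("G", "G", "G"),
    c("A", "G", "A"),                   # GG[A/G]: both glycine -> ss
    c("T", "C", "T"),                   # [T/C]TA: Leu/Leu -> ss
    c("T", "T", "T"), c("A", "A", "A")
  ))
  snps <- detect_snp_sites(reps)
  out <- classify_ns_ss(snps, reps, ref)
  expect_equal(out$class[out$position == 2L], "ss")
  expect_equal(out$class[out$position == 3L], "ss")

  # first-position change altering the residue -> ns
  reps2 <- reps_from_columns(list(
    c("G", "C", "G"),                   # [G/C]GA: Gly vs Arg -> ns
    c("G", "G", "G"), c("A", "A", "A"),
    c("T", "T", "T"), c("T", "T", "T"), c("A", "A", "A")
  ))
  out2 <- classify_ns_ss(detect_snp_sites(reps2), reps2, ref)
  expect_equal(out2$class, "ns")

  # site with three alleles where one substitution is silent: still ns
  reps3 <- reps_from_columns(list(
    c("G", "G", "G", "G"), c("G", "G", "G", "G"),
    c("A", "G", "T", "A"),              # GGA/GGG silent, GGT silent too
    c("T", "T", "T", "T"), c("T", "T", "T", "T"), c("A", "A", "A", "A")
  ))
  out3 <- classify_ns_ss(detect_snp_sites(reps3), reps3, ref)
  expect_equal(out3$class, "ss")       # all third-position Gly codons
  reps4 <- reps_from_columns(list(
    c("G", "G", "G", "G"),
    c("G", "G", "A", "G"),              # G[G/A]A: Gly vs Glu -> ns
    c("A", "G", "A", "A"),              # also polymorphic, silent
    c("T", "T", "T", "T"), c("T", "T", "T", "T"), c("A", "A", "A", "A")
  ))
  out4 <- classify_ns_ss(detect_snp_sites(reps4), reps4, ref)
  expect_equal(out4$class[out4$position == 1L], "ns")
  expect_equal(out4$class[out4$position == 2L], "ss")
})

test_that("sites in a trailing partial codon are excluded with a warning", {
  ref <- reference_genes("g", "mt", "GGATTAC", complete_cds = FALSE)
  reps <- reps_from_columns(list(
    c("G", "G"), c("G", "G"), c("A", "A"),
    c("T", "T"), c("T", "T"), c("A", "A"),
    c("C", "T")                          # in the dangling 7th base
  ))
  snps <- detect_snp_sites(reps)
  expect_warning(out <- classify_ns_ss(snps, reps, ref), "complete codon")
  expect_true(is.na(out$class[out$position == 6L]))
})

test_that("n_ns + n_ss = n_snp holds for every gene across random cohorts", {
  for (seed in c(7L, 77L)) {
    co <- synthesize_cohort(small_config(seed = seed))
    an <- analyze_cohort(co, keep_pileups = FALSE)
    per_gene <- an$gene_stats
    expect_equal(per_gene$n_ns + per_gene$n_ss, per_gene$n_snp)
    expect_true(all(per_gene$n_correspondence <=
                      pmin(per_gene$n_snp, per_gene$n_prnae)))
  }
})

test_that("report totals and percentages are exact arithmetic of the rows", {
  stats <- tibble::tibble(
    gene = c("cox1", "cox3", "cob"), compartment = "mt",
    analyzed_sites = c(1455L, 771L, 1062L),
    n_snp = c(57L, 56L, 72L),
    n_prnae = c(29L, 24L, 19L),
    n_correspondence = c(26L, 24L, 18L))
  rep <- build_variation_report(stats)
  tot <- glance(rep)
  expect_equal(tot$analyzed_sites, 3288L)
  expect_equal(tot$n_snp, 185L)
  expect_equal(tot$n_prnae, 72L)
  expect_equal(tot$n_correspondence, 68L)
  expect_equal(tot$snp_pct, 5.6)
  expect_equal(tot$corr_per_snp_pct, 36.8)
  expect_equal(tot$corr_per_prnae_pct, 94.4)

  zero <- build_variation_report(dplyr::mutate(
    stats, n_snp = 0L, n_correspondence = 0L))
  expect_true(all(zero$snp_pct == 0))
  expect_true(all(zero$corr_per_snp_pct == 0))
})
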