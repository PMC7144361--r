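test_that("k-mer index postings match the L-k+1 count and a naive scan", {
  refs <- reference_genes("g1", "mt", "ACGTACGTACGT")
  idx <- build_index(refs, k = 8)
  # one forward posting per k-mer start: L - k + 1 in total
  starts <- 1:(12 - 8 + 1)
  n_fwd <- sum(vapply(starts, function(s) {
    h <- lookup_kmer(idx, substring("ACGTACGTACGT", s, s + 7))
    sum(h$strand == "+" & h$offset == s - 1L)
  }, numeric(1)))
  expect_equal(n_fwd, 12 - 8 + 1)
  hits <- lookup_kmer(idx, "ACGTACGT")
  fwd <- hits[hits$strand == "+", ]
  expect_setequal(fwd$offset, c(0L, 4L))
  expect_equal(nrow(lookup_kmer(idx, "TTTTTTTT")), 0L)

  # every k-mer's postings equal a brute-force substring scan on a 200 bp ref
  set.seed(55)
  refs <- reference_genes("g1", "mt", random_dna_test(201L))
  k <- 12L
  idx <- build_index(refs, k)
  seqs <- c(`+` = refs$sequence, `-` = revcomp_test(refs$sequence))
  probe <- vapply(sample.int(201 - k, 25), function(s)
    substring(refs$sequence, s, s + k - 1), character(1))
  for (km in probe) {
    got <- lookup_kmer(idx, km)
    for (strand in c("+", "-")) {
      naive <- integer(0)
      s <- seqs[[strand]]
      for (o in 0:(nchar(s) - k)) {
        if (substring(s, o + 1, o + k) == km) naive <- c(naive, o)
      }
      expect_setequal(got$offset[got$strand == strand], naive)
    }
  }
  expect_error(build_index(refs, k = 7), "at least 8")
})

test_that("reads identical to reference substrings map with 0 mismatches", {
  refs <- toy_references()
  idx <- build_index(refs)
  r <- substring(refs$sequence[1], 41, 110)
  pl <- map_read(r, idx)
  expect_true(pl$mapped)
  expect_equal(pl$gene_id, "geneA")
  expect_equal(pl$start, 40L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$n_mismatch, 0L)

  # reverse-complemented read maps to the same place on the minus strand
  pl2 <- map_read(revcomp_test(r), idx)
  expect_equal(pl2$start, 40L)
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$query, r)

  # a read over the mismatch threshold everywhere is unmapped
  bad <- paste0(substring(r, 1, 30), strrep("A", 40))
  if (map_read(bad, idx)$mapped) skip("flank happened to be A-rich")
  expect_false(map_read(bad, idx)$mapped)
})

test_that("1000 error-free reads are placed at their generating coordinates", {
  set.seed(77)
  refs <- reference_genes(c("g1", "g2"), c("mt", "pt"),
                          random_dna_test(c(900L, 600L)))
  idx <- build_index(refs)
  n <- 1000L
  gi <- sample(1:2, n, replace = TRUE)
  rl <- sample(75:100, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(refs$length[gi[i]] - rl[i] + 1L, 1L) - 1L, integer(1))
  fwd <- substring(refs$sequence[gi], start + 1L, start + rl)
  flip <- runif(n) < 0.5
  reads <- ifelse(flip, revcomp_test(fwd), fwd)
  pl <- map_reads(stats::setNames(reads, paste0("r", 1:n)), idx)
  # reads whose sequence occurs uniquely must land exactly where they came from
  uniq <- !duplicated(fwd) & !duplicated(fwd, fromLast = TRUE)
  expect_true(all(pl$mapped[uniq]))
  expect_equal(pl$gene_id[uniq], refs$gene_id[gi][uniq])
  expect_equal(pl$start[uniq], start[uniq])
  expect_equal(pl$n_mismatch[uniq], rep(0L, sum(uniq)))
  expect_equal(pl$strand[uniq], ifelse(flip, "-", "+")[uniq])
})

test_that("pileup counts no more bases than were read, on the right strand", {
  co <- synthesize_cohort(small_config(seed = 13L))
  idx <- build_index(co$references)
  d <- co$reads[co$reads$sample_id == "OK01", ]
  pu <- pileup_sample(d[, c("read_id", "sequence")], idx, co$references,
                      "OK01")
  total_counted <- sum(vapply(pu$counts, sum, numeric(1)))
  expect_lte(total_counted, sum(nchar(d$sequence)))
  pl <- attr(pu, "placements")
  expect_equal(total_counted, sum(nchar(pl$query[pl$mapped])))
})

test_that("internal placements serialized to SAM re-ingest to the identical pileup", {
  co <- synthesize_cohort(small_config(seed = 29L))
  idx <- build_index(co$references)
  d <- co$reads[co$reads$sample_id == "KR01", ][1:120, ]
  pu <- pileup_sample(d[, c("read_id", "sequence")], idx, co$references,
                      "KR01")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(attr(pu, "placements"), co$references, sam)
  pu2 <- ingest_sam(sam, co$references, "KR01")
  expect_equal(pu2$counts, pu$counts, ignore_attr = FALSE)
})

test_that("ambiguous best placements are discarded by the unique-best policy", {
  # two identical genes: every read maps equally well to both
  set.seed(5)
  s <- random_dna_test(300L)
  refs <- reference_genes(c("dupA", "dupB"), c("mt", "mt"), c(s, s))
  idx <- build_index(refs)
  r <- substring(s, 100, 180)
  expect_false(map_read(r, idx)$mapped)
})
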