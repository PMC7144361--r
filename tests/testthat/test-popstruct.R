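test_that("concatenation preserves length and distance is order-invariant", {
  set.seed(90)
  genes <- c("cox1", "cox3", "cob")
  lens <- c(90L, 60L, 120L)
  reps <- dplyr::bind_rows(lapply(1:3, function(i) tibble::tibble(
    gene_id = genes[i], sample_id = paste0("s", 1:4),
    sequence = random_dna_test(rep(lens[i], 4)))))
  cc <- concatenate_representatives(reps, genes)
  expect_equal(unique(nchar(cc$sequence)), sum(lens))
  cc1 <- concatenate_representatives(reps[reps$gene_id == genes[1], ],
                                     genes[1])
  expect_equal(cc1$sequence,
               reps$sequence[reps$gene_id == genes[1]])   # single gene
  d1 <- distance_matrix(cc)
  d2 <- distance_matrix(concatenate_representatives(reps, rev(genes)))
  expect_equal(d1, d2)
  expect_error(concatenate_representatives(reps[-1, ], genes), "s1")
})

test_that("p-distance matches closed forms and a naive oracle with Ns", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_warning(expect_equal(p_distance("NNNN", "ACGT"), 0),
                 "no comparable")
  expect_error(p_distance("AC", "ACG"), "unequal")
  set.seed(31)
  for (i in 1:10) {
    a <- paste0(sample(c("A", "C", "G", "T", "N"), 100, replace = TRUE,
                       prob = c(.23, .23, .23, .23, .08)), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T", "N"), 100, replace = TRUE,
                       prob = c(.23, .23, .23, .23, .08)), collapse = "")
    expect_equal(p_distance(a, b), naive_p_distance(a, b))
  }
  # the matrix path (via ape) agrees with the scalar implementation
  cc <- tibble::tibble(sample_id = c("x", "y"),
                       sequence = c("ACGTNACGTA", "ACTTNACGTN"))
  dm <- distance_matrix(cc)
  expect_equal(dm["x", "y"],
               p_distance(cc$sequence[1], cc$sequence[2]))
})

test_that("NJ recovers additive trees: closed form at n=3, exact at n=4", {
  # 3 taxa: unique unrooted topology with additive branch lengths
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), letters[1:3])
  ed <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(ed[c("a", "b", "c")]), c(1, 2, 3))

  # 4 taxa with additive distances: generating topology recovered
  tru <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  d4 <- ape::cophenetic.phylo(tru)
  tr4 <- nj_tree(d4)
  expect_equal(ape::dist.topo(ape::unroot(tru), tr4), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite")
})

test_that("NJ equals exhaustive topology search on additive matrices (n 5..7)", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (n in 5:7) {
    tru <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(tru)
    got <- nj_tree(d)
    # oracle: among all unrooted topologies, exactly those with a perfect
    # least-squares fit are additive-consistent
    all_tr <- phangorn::allTrees(n, rooted = FALSE,
                                 tip.label = tru$tip.label)
    fits <- vapply(all_tr, function(t) {
      f <- phangorn::nnls.tree(d, t, method = "unrooted")
      sum((ape::cophenetic.phylo(f)[rownames(d), colnames(d)] - d)^2)
    }, numeric(1))
    best <- which(fits < 1e-10)
    expect_length(best, 1L)
    expect_equal(ape::dist.topo(all_tr[[best]], got), 0, ignore_attr = TRUE)
  }
})

test_that("two interleaved populations split into the two NJ sides", {
  set.seed(64)
  L <- 800L
  base <- strsplit(random_dna_test(L), "", fixed = TRUE)[[1]]
  diverged <- base
  flip <- sample.int(L, 8L)   # ~1% divergence between populations
  diverged[flip] <- vapply(base[flip], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  make_sample <- function(h) {
    ch <- h
    p <- sample.int(L, 2L)    # private noise
    ch[p] <- vapply(ch[p], function(b)
      setdiff(c("A", "C", "G", "T"), b)[2], character(1))
    paste0(ch, collapse = "")
  }
  cc <- tibble::tibble(
    sample_id = c(rbind(paste0("p1_", 1:5), paste0("p2_", 1:5))),
    sequence = c(rbind(vapply(1:5, function(i) make_sample(base),
                              character(1)),
                       vapply(1:5, function(i) make_sample(diverged),
                              character(1)))))
  tr <- nj_tree(distance_matrix(cc))
  # the edge separating the populations must exist: check monophyly both ways
  bp <- ape::prop.part(tr)
  sides <- lapply(bp, function(p) sort(tr$tip.label[p]))
  p1 <- sort(cc$sample_id[1:10 %% 2 == 1])
  p2 <- sort(cc$sample_id[1:10 %% 2 == 0])
  expect_true(any(vapply(sides, identical, logical(1), p1)) ||
                any(vapply(sides, identical, logical(1), p2)))
})

test_that("bootstrap supports are reproducible, bounded and order-invariant", {
  set.seed(46)
  L <- 400L
  seqs <- random_dna_test(rep(L, 1))
  base <- strsplit(seqs, "", fixed = TRUE)[[1]]
  cc <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    sequence = vapply(1:6, function(i) {
      ch <- base
      if (i > 3) ch[1:20] <- "T"      # deep split between s1-3 and s4-6
      ch[sample.int(L, 1)] <- "A"
      paste0(ch, collapse = "")
    }, character(1)))
  b1 <- bootstrap_support(cc, n_replicates = 25L, seed = 99L)
  b2 <- bootstrap_support(cc, n_replicates = 25L, seed = 99L)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  # single replicate: supports only 0 or 100
  b3 <- bootstrap_support(cc, n_replicates = 1L, seed = 4L)
  expect_true(all(b3$support %in% c(0L, 100L)))
  # permuting sample order leaves clade supports unchanged
  perm <- sample.int(nrow(cc))
  b4 <- bootstrap_support(cc[perm, ], n_replicates = 25L, seed = 99L)
  key <- function(b) {
    cl <- symbiovar:::clade_table(b$tree, b$support)
    sup <- stats::setNames(cl$support,
                           vapply(cl$tips, paste, character(1),
                                  collapse = ","))
    sup[order(names(sup))]
  }
  k1 <- key(b1); k4 <- key(b4)
  shared <- intersect(names(k1), names(k4))
  expect_gt(length(shared), 0)
  expect_equal(k1[shared], k4[shared])
})

test_that("cluster assessment reads exclusive supported clades per group", {
  # star tree: no internal structure, every group reports size 1
  star <- ape::read.tree(text = "(a1:1,a2:1,b1:1,b2:1);")
  meta <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2", "c1"),
                         locality_group = c("OK", "OK", "KR", "KR", "YN"))
  out <- assess_clusters(list(tree = star, support = NULL), meta)
  expect_equal(out$clade_size[out$locality_group == "OK"], 1L)
  expect_equal(out$clade_size[out$locality_group == "KR"], 1L)
  # group absent from the tree reports size 0
  expect_equal(out$clade_size[out$locality_group == "YN"], 0L)

  # planted diverged YN pool (strongly discriminating so the planted
  # structure is unambiguous): YN is the only multi-sample exclusive clade
  co <- synthesize_cohort(small_config(seed = 59L,
                                       p_discriminating = 0.5))
  reps <- co$haplotypes[, c("gene_id", "sample_id", "sequence")]
  cc <- concatenate_representatives(reps, co$references$gene_id)
  bs <- bootstrap_support(cc, n_replicates = 50L, seed = 6L)
  cl <- assess_clusters(bs, co$samples, min_support = 70L)
  yn <- cl[cl$locality_group == "YN", ]
  expect_gte(yn$clade_size, 2L)
  expect_gte(yn$clade_support, 70L)
  others <- cl[cl$locality_group != "YN", ]
  expect_true(all(others$clade_size <= 1L))
})
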