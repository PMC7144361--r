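# shared fixtures and independent oracles for the test suite

# a small deterministic two-gene reference set (lengths divisible by 3)
toy_references <- function() {
  set.seed(901)
  reference_genes(
    gene_id = c("geneA", "geneB"),
    compartment = c("mt", "pt"),
    sequence = random_dna_test(c(300L, 240L))
  )
}

random_dna_test <- function(lengths) {
  vapply(lengths, function(L) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# a small cohort configuration that runs in seconds
small_config <- function(seed = 3L, ...) {
  cohort_config(
    n_samples_per_group = c(OK = 4L, KR = 3L, YN = 3L, YS = 2L),
    genes = tibble::tibble(gene_id = c("m1", "p1"),
                           compartment = c("mt", "pt"),
                           length = c(450L, 300L)),
    mt_coverage = 20, pt_coverage = 15,
    n_low_coverage_samples = 1L,
    n_its2_typed_samples = 4L,
    seed = seed,
    ...
  )
}

# brute-force per-column tally over explicitly laid-out reads:
# reads is a list of list(start = 0-based, seq = aligned bases)
naive_column_tally <- function(reads, ref_len) {
  m <- matrix(0L, nrow = ref_len, ncol = 5L,
              dimnames = list(NULL, c("A", "C", "G", "T", "other")))
  for (r in reads) {
    ch <- strsplit(r$seq, "", fixed = TRUE)[[1]]
    for (j in seq_along(ch)) {
      col <- match(ch[j], c("A", "C", "G", "T"))
      if (is.na(col)) col <- 5L
      row <- r$start + j
      m[row, col] <- m[row, col] + 1L
    }
  }
  m
}

# naive p-distance: per-column loop
naive_p_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- 0L; mm <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") && bv[i] %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (av[i] != bv[i]) mm <- mm + 1L
    }
  }
  if (n == 0L) 0 else mm / n
}

# quadratic-time affine-gap Smith-Waterman oracle; a gap of length L costs
# gap_open + gap_extend * L (first gap base pays both)
sw_oracle <- function(a, b, match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)    # best ending in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)    # best ending in gap in a (b consumed)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

revcomp_test <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(ch) paste0(rev(ch), collapse = ""), character(1)))
}
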