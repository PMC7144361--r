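#' Build a k-mer index over reference genes
#'
#' Every exact k-mer of every reference (both strands) is recorded with its
#' gene and 0-based offset. The index backs the seed-and-extend short-read
#' mapper ([map_reads()]), a deliberately simple stand-in for a production
#' aligner: the downstream analysis is site-wise on fixed reference
#' coordinates, so ungapped placements suffice.
#'
#' @param references tibble from [reference_genes()].
#' @param k k-mer size (default 21; must be at least 8).
#' @return an object of class `sv_index`.
#' @export
build_index <- function(references, k = 21L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be at least 8")
  if (any(references$length < k)) {
    stop("k exceeds the length of the shortest reference gene")
  }
  kmers <- character(0); g <- integer(0); p <- integer(0); s <- integer(0)
  for (i in seq_len(nrow(references))) {
    for (strand in 1:2) {
      seqs <- if (strand == 1L) references$sequence[i] else
        revcomp(references$sequence[i])
      L <- nchar(seqs)
      starts <- seq_len(L - k + 1L)
      kmers <- c(kmers, substring(seqs, starts, starts + k - 1L))
      g <- c(g, rep.int(i, length(starts)))
      p <- c(p, starts - 1L)
      s <- c(s, rep.int(strand, length(starts)))
    }
  }
  # store postings as row-major (gene, pos, strand) triples for fast expansion
  triples <- as.vector(rbind(g, p, s))
  env <- list2env(split(triples, rep(kmers, each = 3L)), hash = TRUE)
  structure(
    list(k = k, env = env,
         gene_ids = references$gene_id,
         gene_len = references$length,
         gene_seq = references$sequence),
    class = "sv_index"
  )
}

#' Look up the posting list of one k-mer
#'
#' @param index an `sv_index`.
#' @param kmer a single k-mer string.
#' @return tibble with columns `gene_id`, `offset` (0-based), `strand`
#'   (`"+"` for the forward reference strand, `"-"` for its reverse
#'   complement, offsets in that strand's own coordinates); zero rows when the
#'   k-mer is absent.
#' @export
lookup_kmer <- function(index, kmer) {
  v <- get0(toupper(kmer), envir = index$env, ifnotfound = NULL)
  if (is.null(v)) {
    return(tibble::tibble(gene_id = character(0), offset = integer(0),
                          strand = character(0)))
  }
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  tibble::tibble(gene_id = index$gene_ids[m[, 1]],
                 offset = as.integer(m[, 2]),
                 strand = c("+", "-")[m[, 3]])
}

# raw byte -> pileup column (A=1 C=2 G=3 T=4 other=5)
base_column_lut <- local({
  lut <- rep.int(5L, 256)
  lut[utf8ToInt("A") + 1L] <- 1L; lut[utf8ToInt("C") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L; lut[utf8ToInt("T") + 1L] <- 4L
  lut
})

#' Map reads to the reference genes by seed-and-extend
#'
#' Up to three non-overlapping k-mer seeds per read (first, middle, last) are
#' probed against the index; every seed hit is extended ungapped over the full
#' read length on the hit's strand. The best placement is the one with fewest
#' mismatches; a read is rejected as unmapped when its best mismatch count
#' exceeds `ceiling(max_mismatch_rate * read_length)` or when two distinct
#' placements tie for best (unique-best policy, which keeps paralog
#' cross-talk out of the pileups).
#'
#' @param reads character vector of read sequences (names used as read ids),
#'   or a tibble with columns `read_id` and `sequence`.
#' @param index an `sv_index` from [build_index()].
#' @param max_mismatch_rate maximum tolerated mismatches per base
#'   (default 0.04).
#' @return tibble with one row per read: `read_id`, `mapped`, `gene_id`,
#'   `start` (0-based), `strand`, `n_mismatch`, and `query` (the read
#'   oriented to the forward reference strand; `NA` when unmapped).
#' @export
map_reads <- function(reads, index, max_mismatch_rate = 0.04) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$sequence
  } else {
    ids <- names(reads)
  }
  reads <- toupper(reads)
  n <- length(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  out <- tibble::tibble(read_id = ids, mapped = FALSE,
                        gene_id = NA_character_, start = NA_integer_,
                        strand = NA_character_, n_mismatch = NA_integer_,
                        query = NA_character_)
  k <- index$k
  rl <- nchar(reads)
  eligible <- which(rl >= k)
  if (length(eligible) == 0) return(out)

  rc <- character(n)
  rc[eligible] <- revcomp(reads[eligible])

  cand_read <- integer(0); cand_g <- integer(0)
  cand_start <- integer(0); cand_strand <- integer(0)
  offs <- cbind(0L, (rl - k) %/% 2L, rl - k)
  for (j in 1:3) {
    o <- offs[eligible, j]
    if (j > 1) {
      fresh <- o != offs[eligible, j - 1L]   # skip duplicate seed offsets
    } else fresh <- rep.int(TRUE, length(o))
    idx <- eligible[fresh]; o <- o[fresh]
    if (length(idx) == 0) next
    kmers <- substring(reads[idx], o + 1L, o + k)
    hits <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
    lens <- lengths(hits) %/% 3L
    keep <- lens > 0L
    if (!any(keep)) next
    trip <- matrix(unlist(hits[keep], use.names = FALSE), ncol = 3L,
                   byrow = TRUE)
    ridx <- rep.int(idx[keep], lens[keep])
    roff <- rep.int(o[keep], lens[keep])
    g <- trip[, 1]; pos <- trip[, 2]; strand <- trip[, 3]
    start <- ifelse(strand == 1L, pos - roff,
                    index$gene_len[g] - (pos - roff) - rl[ridx])
    cand_read <- c(cand_read, ridx)
    cand_g <- c(cand_g, g)
    cand_start <- c(cand_start, as.integer(start))
    cand_strand <- c(cand_strand, strand)
  }
  if (length(cand_read) == 0) return(out)

  # in-bounds placements, deduplicated across seeds
  ok <- cand_start >= 0L & cand_start + rl[cand_read] <= index$gene_len[cand_g]
  cand_read <- cand_read[ok]; cand_g <- cand_g[ok]
  cand_start <- cand_start[ok]; cand_strand <- cand_strand[ok]
  if (length(cand_read) == 0) return(out)
  key <- ((cand_read * 64 + cand_g) * 4 + cand_strand) * 8192 + cand_start
  dup <- duplicated(key)
  cand_read <- cand_read[!dup]; cand_g <- cand_g[!dup]
  cand_start <- cand_start[!dup]; cand_strand <- cand_strand[!dup]

  query <- ifelse(cand_strand == 1L, reads[cand_read], rc[cand_read])
  refsub <- substring(index$gene_seq[cand_g], cand_start + 1L,
                      cand_start + rl[cand_read])
  mm <- string_mismatches(query, refsub)
  thr <- ceiling(max_mismatch_rate * rl[cand_read])
  keep <- mm <= thr
  if (!any(keep)) return(out)
  cr <- cand_read[keep]; cg <- cand_g[keep]; cs <- cand_start[keep]
  cstr <- cand_strand[keep]; cq <- query[keep]; cmm <- mm[keep]

  ord <- order(cr, cmm)
  best <- ord[!duplicated(cr[ord])]
  # count candidates achieving the per-read minimum: unique-best policy
  min_mm <- integer(n); min_mm[cr[best]] <- cmm[best]
  at_min <- cmm == min_mm[cr]
  n_at_min <- tabulate(cr[at_min], nbins = n)
  unique_best <- best[n_at_min[cr[best]] == 1L]

  ri <- cr[unique_best]
  out$mapped[ri] <- TRUE
  out$gene_id[ri] <- index$gene_ids[cg[unique_best]]
  out$start[ri] <- cs[unique_best]
  out$strand[ri] <- c("+", "-")[cstr[unique_best]]
  out$n_mismatch[ri] <- cmm[unique_best]
  out$query[ri] <- cq[unique_best]
  out
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read a single DNA string.
#' @return one-row tibble in the [map_reads()] layout.
#' @export
map_read <- function(read, index, max_mismatch_rate = 0.04) {
  map_reads(stats::setNames(read, "read1"), index, max_mismatch_rate)
}

#' Accumulate a per-site base-count pileup from placements
#'
#' @param placements tibble in the [map_reads()] layout (unmapped rows are
#'   ignored); `query` must be oriented to the forward reference strand, as
#'   [map_reads()] returns it.
#' @param references tibble from [reference_genes()].
#' @param sample_id sample label attached to the result.
#' @return tibble with columns `gene_id`, `sample_id` and `counts`, a
#'   list-column of `gene_length x 5` integer matrices (columns
#'   `A,C,G,T,other`).
#' @export
pileup_from_placements <- function(placements, references,
                                   sample_id = NA_character_) {
  placements <- placements[which(placements$mapped), ]
  counts <- lapply(seq_len(nrow(references)), function(i) {
    L <- references$length[i]
    rows <- which(placements$gene_id == references$gene_id[i])
    if (length(rows) == 0) {
      m <- matrix(0L, nrow = L, ncol = 5L)
    } else {
      q <- placements$query[rows]
      ql <- nchar(q)
      pos0 <- sequence(ql, from = placements$start[rows] + 1L) - 1L
      col <- base_column_lut[as.integer(charToRaw(paste0(q, collapse = ""))) + 1L]
      m <- matrix(tabulate(pos0 * 5L + col, nbins = L * 5L),
                  nrow = L, ncol = 5L, byrow = TRUE)
    }
    colnames(m) <- c("A", "C", "G", "T", "other")
    m
  })
  tibble::tibble(gene_id = references$gene_id, sample_id = sample_id,
                 counts = counts)
}

#' Map one sample's paired-end reads and build its pileup
#'
#' @param reads either a tibble with columns `read_id`, `sequence` (a `mate`
#'   column is allowed and ignored: mates are mapped as independent reads), or
#'   a length-2 character vector of R1/R2 FASTQ paths.
#' @param index an `sv_index`.
#' @param references tibble from [reference_genes()].
#' @param sample_id sample label.
#' @param max_mismatch_rate see [map_reads()].
#' @return tibble as from [pileup_from_placements()], with the placements
#'   attached as attribute `"placements"`.
#' @export
pileup_sample <- function(reads, index, references,
                          sample_id = NA_character_,
                          max_mismatch_rate = 0.04) {
  if (is.character(reads)) {
    stopifnot(length(reads) == 2)
    r1 <- read_fastq(reads[1]); r2 <- read_fastq(reads[2])
    if (nrow(r1) != nrow(r2)) {
      stop("mate FASTQ files have unequal record counts: ",
           nrow(r1), " vs ", nrow(r2))
    }
    reads <- tibble::tibble(read_id = c(r1$id, r2$id),
                            sequence = c(r1$sequence, r2$sequence))
  }
  pl <- map_reads(reads, index, max_mismatch_rate)
  out <- pileup_from_placements(pl, references, sample_id)
  attr(out, "placements") <- pl
  out
}

#' Per-site read depth of one pileup matrix
#'
#' @param counts a `L x 5` pileup count matrix.
#' @return integer vector of row sums.
#' @export
pileup_depth <- function(counts) as.integer(rowSums(counts))
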