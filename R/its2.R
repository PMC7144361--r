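#' Best local-alignment score of a read against one reference
#'
#' Smith-Waterman-style local alignment score (via Biostrings) under an
#' affine scheme: match +2, mismatch -3, gap open -5, gap extend -2 (a gap of
#' length `L` costs `5 + 2 L`). Both strands of the read are scored by
#' default and the better score returned. This raw score is the package's
#' stand-in for a BLAST bit-score/E-value: no database statistics are
#' computed.
#'
#' @param read,ref non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   positive).
#' @param both_strands also score the reverse complement (default `TRUE`).
#' @return a single numeric score.
#' @export
score_read <- function(read, ref, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2, both_strands = TRUE) {
  score_reads(read, ref, match, mismatch, gap_open, gap_extend, both_strands)
}

#' Vectorised local-alignment scores of many reads against one reference
#' @keywords internal
score_reads <- function(reads, ref, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2, both_strands = TRUE) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pat <- Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(ref), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  if (!both_strands) return(fwd)
  rev <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(pat), Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  pmax(fwd, rev)
}

#' Assign ITS2 types to reads by highest alignment score
#'
#' Each read is scored against every ITS2 reference; the type of the
#' highest-scoring reference is assigned when the score reaches `min_score`.
#' An exact score tie across different types leaves the read unassigned
#' (conservative typing); ties among references of the same type are
#' harmless.
#'
#' @param reads tibble with columns `sample_id`, `read_id`, `sequence`.
#' @param its2_refs tibble with columns `type`, `ref_id`, `sequence` (as
#'   read from a FASTA with `type|id` headers via [read_its2_references()]).
#' @param min_score minimum score for assignment (default 100).
#' @param ... scoring parameters passed to [score_read()].
#' @return list of class `sv_its2` with `assignments` (per read: `read_id`,
#'   `sample_id`, `best_type`, `best_score`, `n_tied`, `assigned`) and
#'   `sample_types` (per sample x type read counts, wide tibble).
#' @export
assign_its2_types <- function(reads, its2_refs, min_score = 100, ...) {
  if (nrow(its2_refs) == 0) stop("empty ITS2 reference set")
  scores <- vapply(seq_len(nrow(its2_refs)), function(j) {
    score_reads(reads$sequence, its2_refs$sequence[j], ...)
  }, numeric(nrow(reads)))
  if (nrow(reads) == 1L) scores <- matrix(scores, nrow = 1)
  best_score <- apply(scores, 1, max)
  n_tied <- integer(nrow(reads))
  best_type <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    at_max <- which(scores[i, ] == best_score[i])
    types <- unique(its2_refs$type[at_max])
    n_tied[i] <- length(types)
    best_type[i] <- if (length(types) == 1) types else NA_character_
  }
  assigned <- best_score >= min_score & !is.na(best_type)
  assignments <- tibble::tibble(
    read_id = reads$read_id, sample_id = reads$sample_id,
    best_type = ifelse(assigned, best_type, NA_character_),
    best_score = best_score, n_tied = n_tied, assigned = assigned
  )
  tab <- dplyr::count(assignments[assignments$assigned, ],
                      .data$sample_id, .data$best_type)
  sample_types <- tidyr::pivot_wider(tab, names_from = "best_type",
                                     values_from = "n", values_fill = 0L)
  structure(list(assignments = assignments, sample_types = sample_types,
                 min_score = min_score),
            class = "sv_its2")
}

#' Count samples with enough assigned ITS2 reads
#'
#' @param its2 an `sv_its2` from [assign_its2_types()] (or its
#'   `assignments` tibble).
#' @param min_reads minimum number of assigned reads for a sample to count
#'   (default 2, reading "more than one read" strictly; set 1 for the laxer
#'   reading).
#' @return integer count of typed samples.
#' @export
count_typed_samples <- function(its2, min_reads = 2L) {
  a <- if (inherits(its2, "sv_its2")) its2$assignments else its2
  if (min_reads < 1) stop("min_reads must be >= 1")
  per <- table(a$sample_id[a$assigned])
  sum(per >= min_reads)
}

#' Read ITS2 references from a FASTA with `type|id` headers
#'
#' @param path FASTA path; each header is `type|identifier`.
#' @return tibble with columns `type`, `ref_id`, `sequence`.
#' @export
read_its2_references <- function(path) {
  f <- read_fasta(path)
  tibble::tibble(type = sub("\\|.*$", "", f$id), ref_id = f$id,
                 sequence = f$sequence)
}
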