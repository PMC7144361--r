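#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character vectors of A/C/G/T (IUPAC
#' ambiguity codes are complemented too, via Biostrings).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA of given lengths
#' @keywords internal
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste0(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Split equal-length sequences into a samples x sites character matrix
#'
#' Rows are named by `ids`. All sequences must share one length.
#' @keywords internal
seq_char_matrix <- function(seqs, ids = names(seqs)) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("sequences have differing lengths: ", paste(L, collapse = ", "))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- ids
  m
}

#' Round half away from zero (display convention for report percentages)
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, half-up to one decimal
#' @keywords internal
pct1 <- function(num, den) {
  ifelse(den > 0, round_half_up(100 * num / den, 1), 0)
}

#' Count per-position mismatches between two equal-length character vectors
#' of sequences, fully vectorised.
#'
#' `a[i]` and `b[i]` must have equal nchar. Returns an integer vector.
#' @keywords internal
string_mismatches <- function(a, b) {
  if (length(a) == 0) return(integer(0))
  na <- nchar(a)
  if (!all(na == nchar(b))) stop("paired sequences must have equal lengths")
  ar <- charToRaw(paste0(a, collapse = ""))
  br <- charToRaw(paste0(b, collapse = ""))
  grp <- rep.int(seq_along(a), na)
  mm <- rowsum(as.integer(ar != br), grp, reorder = TRUE)
  out <- integer(length(a))
  out[as.integer(rownames(mm))] <- as.integer(mm)
  out
}
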