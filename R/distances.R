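#' Bounded Levenshtein distance
#'
#' Edit distance between pairs of sequences, computed with a banded dynamic
#' program that abandons once the distance exceeds `kmax`; values greater
#' than `kmax` are reported as `kmax + 1`. Used wherever the pipeline only
#' needs to know whether two sequences are within a small radius (OTU
#' identity, noisy-feature classification, UNOISE skew tests).
#'
#' @param a,b character vectors of equal length (element-wise pairs).
#' @param kmax maximum distance of interest.
#' @return integer vector of `min(distance, kmax + 1)`.
#' @export
seq_dist_bounded <- function(a, b, kmax) {
  stopifnot(kmax >= 0)
  .bounded_levenshtein(as.character(a), as.character(b), as.integer(kmax))
}

#' Bounded Levenshtein distance matrix
#'
#' @param x,y character vectors; result has `length(x)` rows and
#'   `length(y)` columns.
#' @inheritParams seq_dist_bounded
#' @return integer matrix capped at `kmax + 1`.
#' @export
seq_dist_matrix <- function(x, y, kmax) {
  stopifnot(kmax >= 0)
  .dist_bounded_matrix(as.character(x), as.character(y), as.integer(kmax))
}

#' Bounded Hamming distance matrix
#'
#' Positional mismatch counts between equal-length sequences, capped at
#' `kmax + 1`. Errors if any pair differs in length: Hamming distance is
#' only meaningful positionally.
#'
#' @inheritParams seq_dist_matrix
#' @return integer matrix capped at `kmax + 1`.
#' @export
hamming_dist_matrix <- function(x, y, kmax) {
  stopifnot(kmax >= 0)
  .hamming_bounded_matrix(as.character(x), as.character(y), as.integer(kmax))
}

#' Exact Levenshtein distance
#'
#' Thin wrapper over [utils::adist()] (generalized edit distance); used by
#' tests as an independent check of the banded implementation and by
#' operations where no useful bound exists.
#'
#' @param x,y character vectors.
#' @return integer matrix of edit distances.
#' @export
seq_dist_exact <- function(x, y) {
  unname(utils::adist(x, y))
}
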