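#' Test a sequence for an exact two-parent crossover (bimera)
#'
#' A candidate is a bimera if it can be written exactly as a prefix of one
#' parent followed by a suffix of a different parent, with both parents at
#' least twice the candidate's abundance. This is the exact two-parent model
#' used for de novo chimera screening throughout the package.
#'
#' @param candidate candidate sequence.
#' @param parents character vector of potential parent sequences.
#' @param candidate_abundance,parent_abundance abundances used for the 2x
#'   eligibility rule; omit both to skip the abundance test.
#' @return logical.
#' @export
is_bimera <- function(candidate, parents, candidate_abundance = NULL,
                      parent_abundance = NULL) {
  if (length(parents) == 0) return(FALSE)
  eligible <- parents != candidate
  if (!is.null(candidate_abundance) && !is.null(parent_abundance)) {
    eligible <- eligible & parent_abundance >= 2 * candidate_abundance
  }
  if (sum(eligible) < 2) return(FALSE)
  par <- parents[eligible]
  pl <- .lcp_lcs(candidate, par)
  lcp <- pl$lcp
  lcs <- pl$lcs
  L <- nchar(candidate)
  ## need distinct parents i, j with lcp_i >= 1, lcs_j >= 1,
  ## lcp_i + lcs_j >= L (a valid breakpoint then exists)
  oi <- order(-lcp)
  oj <- order(-lcs)
  check <- function(i, j) {
    i != j && lcp[i] >= 1 && lcs[j] >= 1 && lcp[i] + lcs[j] >= L
  }
  if (check(oi[1], oj[1])) return(TRUE)
  if (length(par) >= 2) {
    if (check(oi[1], oj[2])) return(TRUE)
    if (check(oi[2], oj[1])) return(TRUE)
  }
  FALSE
}

#' Flag bimeric sequences in an abundance-ordered set
#'
#' Vectorized screen: each sequence is tested against all sequences with at
#' least twice its abundance.
#'
#' @param sequence character vector, ordered by decreasing abundance.
#' @param abundance numeric vector of abundances.
#' @return logical vector, TRUE where bimeric.
#' @export
flag_bimeras <- function(sequence, abundance) {
  n <- length(sequence)
  flags <- logical(n)
  if (n < 3) return(flags)
  for (i in seq_len(n)) {
    par <- abundance >= 2 * abundance[i]
    par[i] <- FALSE
    if (sum(par) < 2) next
    flags[i] <- is_bimera(sequence[i], sequence[par])
  }
  flags
}

#' Remove bimeric features from a feature table
#'
#' De novo chimera removal over inferred features: features flagged by
#' [is_bimera()] against more abundant features are dropped. Methods place
#' this step differently (inline during clustering for UPARSE-style
#' clustering, after inference for the denoisers, as a separate pre-step on
#' unique reads for plain greedy OTU clustering); this function implements
#' the post-inference placement.
#'
#' @param table a `feature_table`.
#' @return filtered `feature_table` with attribute `n_chimeras_removed`.
#' @export
remove_chimeras <- function(table) {
  flags <- flag_bimeras(table$sequence, table$abundance)
  out <- feature_table(table$sequence[!flags],
                       table$counts[!flags, , drop = FALSE],
                       table$method, table$scope)
  attr(out, "n_chimeras_removed") <- sum(flags)
  out
}
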