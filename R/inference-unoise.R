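#' UNOISE-style denoising parameters
#'
#' @param alpha error-model tuning parameter (default 2); larger alpha
#'   shrinks the abundance skew tolerated at a given distance, so more
#'   sequences survive as distinct features.
#' @return an object of class `unoise_params`.
#' @export
unoise_params <- function(alpha = 2) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha), class = "unoise_params")
}

#' Maximum abundance skew of an error sequence at distance d
#'
#' `beta(d) = 1 / 2^(alpha * d + 1)`: the largest abundance ratio, relative
#' to its correct template, that a sequence at Levenshtein distance `d` may
#' have and still be explained as sequencer error. Strictly decreasing in
#' `d`.
#'
#' @param d integer Levenshtein distance(s).
#' @param alpha tuning parameter.
#' @return numeric vector of skew thresholds.
#' @export
unoise_beta <- function(d, alpha = 2) {
  1 / 2^(alpha * d + 1)
}

#' UNOISE-style abundance-skew denoising
#'
#' In decreasing abundance order, a sequence joins the most abundant
#' centroid whose error model is consistent with it — i.e. whose abundance
#' skew `abundance(s) / abundance(c)` is at most
#' `beta(Levenshtein(s, c))` — and otherwise becomes a new centroid. On
#' ties (several qualifying centroids) the most abundant wins, then
#' lexicographic order of the centroid sequence.
#'
#' @param derep a `derep` set (abundance-ordered).
#' @param p an `unoise_params`.
#' @return a `feature_table` (method `"unoise"`).
#' @export
denoise_unoise <- function(derep, p = unoise_params()) {
  n <- length(derep$sequence)
  assign <- rep(NA_integer_, n)
  centroids <- integer(0)
  if (n > 0) {
    maxlen <- max(nchar(derep$sequence))
    for (i in seq_len(n)) {
      a <- derep$abundance[i]
      hit <- NA_integer_
      if (length(centroids)) {
        ## beta(d) >= skew is only possible up to
        ## d <= (log2(1/skew) - 1) / alpha against the largest centroid
        skew_min <- a / derep$abundance[centroids[1]]
        kmax <- floor((log2(1 / skew_min) - 1) / p$alpha)
        kmax <- as.integer(max(0, min(kmax, maxlen)))
        d <- seq_dist_matrix(derep$sequence[i],
                             derep$sequence[centroids], kmax)[1, ]
        skew <- a / derep$abundance[centroids]
        ok <- which(d <= kmax & skew <= unoise_beta(d, p$alpha))
        if (length(ok)) hit <- ok[1]  # centroids kept in abundance order
      }
      if (!is.na(hit)) {
        assign[i] <- hit
      } else {
        centroids <- c(centroids, i)
        assign[i] <- length(centroids)
      }
    }
  }
  table_from_assignment(derep, assign,
                        features = derep$sequence[centroids],
                        method = "unoise", scope = "pooled")
}
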