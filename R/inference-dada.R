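#' DADA-style iterative denoising parameters
#'
#' @param omega p-value threshold below which a sequence seeds a new
#'   cluster (default 1e-40); 0 disables splitting entirely.
#' @param max_iterations outer error-model re-estimation rounds.
#' @param init_error initial (pessimistic) per-base substitution rate of
#'   the worst-case error matrix.
#' @param err_floor lower bound applied to re-estimated transition
#'   probabilities, keeping the matrix strictly inside (0, 1).
#' @return an object of class `dada_params`.
#' @export
dada_params <- function(omega = 1e-40, max_iterations = 10L,
                        init_error = 0.05, err_floor = 1e-7) {
  stopifnot(omega >= 0, omega < 1, max_iterations >= 1,
            init_error > 0, init_error < 1)
  structure(list(omega = omega, max_iterations = as.integer(max_iterations),
                 init_error = init_error, err_floor = err_floor),
            class = "dada_params")
}

## log P(X >= a | X >= 1) for X ~ Poisson(E), with E given in log space
.log_cond_pois_tail <- function(a, logE) {
  if (a <= 1) return(0)
  if (logE > -18) {
    E <- exp(logE)
    num <- ppois(a - 1, E, lower.tail = FALSE, log.p = TRUE)
    den <- log(-expm1(-E))
    p <- num - den
    if (is.finite(p)) return(p)
  }
  ## tiny-E asymptotics: P(X >= a) ~ E^a / a!, P(X >= 1) ~ E
  (a - 1) * logE - lfactorial(a)
}

## 4x4 (from, to) error matrix with uniform off-diagonal rate
.uniform_error_matrix <- function(err) {
  m <- matrix(err / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 1 - err
  m
}

## core split/reassign loop on one equal-length group
.dada_group <- function(seqs, abundance, p) {
  n <- length(seqs)
  if (n == 1) {
    return(list(centroids = 1L, assign = 1L, converged = TRUE))
  }
  E <- .uniform_error_matrix(p$init_error)
  log_omega <- if (p$omega > 0) log(p$omega) else -Inf
  converged <- FALSE
  centroids <- 1L
  assign <- rep(1L, n)
  for (iter in seq_len(p$max_iterations)) {
    centroids <- 1L                # most abundant seeds the single cluster
    assign <- rep(1L, n)
    logE <- log(E)
    ll <- .loglambda_matrix(seqs, seqs[centroids], logE)
    repeat {
      assign <- max.col(ll, ties.method = "first")
      logp <- rep(0, n)
      for (i in seq_len(n)) {
        if (i %in% centroids) next
        c_ab <- abundance[centroids[assign[i]]]
        logp[i] <- .log_cond_pois_tail(abundance[i],
                                       ll[i, assign[i]] + log(c_ab))
      }
      worst <- which.min(logp)
      if (p$omega > 0 && logp[worst] < log_omega &&
          !(worst %in% centroids)) {
        centroids <- c(centroids, worst)
        ll <- cbind(ll, .loglambda_matrix(seqs, seqs[worst], logE))
      } else {
        break
      }
    }
    ## re-estimate the error matrix from within-cluster transitions
    tc <- .transition_counts(seqs, seqs[centroids], assign, abundance)
    rs <- rowSums(tc)
    newE <- tc / ifelse(rs > 0, rs, 1)
    newE[newE < p$err_floor] <- p$err_floor
    newE <- newE / rowSums(newE)
    dimnames(newE) <- dimnames(E)
    if (max(abs(newE - E)) < 1e-7) {
      converged <- TRUE
      E <- newE
      break
    }
    E <- newE
  }
  list(centroids = centroids, assign = assign, converged = converged)
}

#' DADA-style iterative error-model denoising
#'
#' Alternates between clustering sequences under a 4x4 base-transition
#' error model and re-estimating that model from the clustering, starting
#' from a pessimistic worst-case matrix. Within each clustering pass, all
#' sequences start in one cluster seeded by the most abundant sequence; the
#' abundance p-value of each non-centroid sequence is the Poisson tail
#' `P(X >= abundance(s) | X >= 1)` with mean `lambda * abundance(centroid)`,
#' where `lambda` is the per-base product probability of reading `s` from
#' its centroid. If the smallest p-value is below `omega`, that sequence
#' seeds a new cluster and all sequences reassign to the centroid
#' maximizing `lambda`; this repeats to a fixpoint. The outer loop stops
#' when the error matrix stabilizes (max absolute change < 1e-7) or after
#' `max_iterations`, in which case the result carries a `converged = FALSE`
#' attribute and a warning is raised.
#'
#' Sequences of different lengths are processed as independent groups (the
#' model is positional). Dereplicated input carries no per-base qualities,
#' so the error matrix is quality-marginalized: one substitution
#' probability per (from, to) base pair.
#'
#' @param derep a `derep` set (abundance-ordered), conventionally from a
#'   single sample.
#' @param p a `dada_params`.
#' @return a `feature_table` (method `"dada"`).
#' @export
denoise_dada <- function(derep, p = dada_params()) {
  n <- length(derep$sequence)
  if (n == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = ncol(derep$counts),
                     dimnames = list(NULL, colnames(derep$counts)))
    return(feature_table(character(0), counts, "dada", "per-sample"))
  }
  lens <- nchar(derep$sequence)
  assign_global <- rep(NA_integer_, n)
  features <- character(0)
  converged <- TRUE
  for (L in unique(lens)) {
    idx <- which(lens == L)
    res <- .dada_group(derep$sequence[idx], derep$abundance[idx], p)
    converged <- converged && res$converged
    offset <- length(features)
    features <- c(features, derep$sequence[idx][res$centroids])
    assign_global[idx] <- offset + res$assign
  }
  if (!converged) {
    warning("error model did not stabilize within max_iterations")
  }
  out <- table_from_assignment(derep, assign_global, features = features,
                               method = "dada", scope = "per-sample")
  attr(out, "converged") <- converged
  out
}
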