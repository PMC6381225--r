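#' Minimum-entropy decomposition parameters
#'
#' @param min_substantive_abundance_frac clusters below this fraction of
#'   all dataset reads are discarded as noise (default 0.0002, i.e. 0.02%).
#' @param entropy_threshold per-column Shannon entropy (nats) above which a
#'   cluster is divided. Either a single number (default 0.2) or a function
#'   `f(abundance)` returning a threshold for the cluster, so alternative
#'   dynamic rules can be plugged in. The fixed default is a package choice,
#'   not a property of any published decomposition tool.
#' @return an object of class `med_params`.
#' @export
med_params <- function(min_substantive_abundance_frac = 2e-4,
                       entropy_threshold = 0.2) {
  stopifnot(min_substantive_abundance_frac >= 0,
            min_substantive_abundance_frac < 1)
  structure(list(min_substantive_abundance_frac = min_substantive_abundance_frac,
                 entropy_threshold = entropy_threshold),
            class = "med_params")
}

MED_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Shannon entropy of an alignment column
#'
#' `-sum p ln p` over the observed symbols (natural log), optionally
#' weighted by read abundance.
#'
#' @param column character vector of symbols (bases and `-` gaps).
#' @param weights optional abundance weights.
#' @return entropy in nats.
#' @export
shannon_column_entropy <- function(column, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(column))
  tot <- rowsum(weights, column)
  p <- tot / sum(tot)
  p <- p[p > 0]
  -sum(p * log(p))
}

## weighted entropy of every column of an integer symbol matrix subset
.column_entropies <- function(mat, rows, weights) {
  m <- mat[rows, , drop = FALSE]
  w <- weights[rows]
  tot <- sum(w)
  vapply(seq_len(ncol(m)), function(j) {
    s <- rowsum(w, m[, j])
    p <- s / tot
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Minimum-entropy decomposition
#'
#' Pads sequences with terminal gaps to a common length, then recursively
#' divides the data: the highest-entropy alignment column is found and, if
#' its entropy exceeds the cluster's threshold, the cluster is partitioned
#' by the symbol at that column (making the offending column's entropy zero
#' in each child) and the children are decomposed in turn. Clusters whose
#' final abundance falls below `min_substantive_abundance_frac` of
#' `total_reads` are discarded as noise. Each surviving cluster is reported
#' as its most abundant member sequence.
#'
#' @param derep a `derep` set (abundance-ordered).
#' @param p a `med_params`.
#' @param total_reads dataset read total used for the abundance floor;
#'   defaults to the reads in `derep`. Under pooled processing this is the
#'   pooled total, which is what makes the method's results depend on which
#'   samples are processed together.
#' @return a `feature_table` (method `"med"`).
#' @export
decompose_med <- function(derep, p = med_params(), total_reads = NULL) {
  n <- length(derep$sequence)
  if (n == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = ncol(derep$counts),
                     dimnames = list(NULL, colnames(derep$counts)))
    return(feature_table(character(0), counts, "med", "pooled"))
  }
  if (is.null(total_reads)) total_reads <- sum(derep$abundance)
  floor_reads <- p$min_substantive_abundance_frac * total_reads
  thr <- p$entropy_threshold
  thr_fun <- if (is.function(thr)) thr else function(ab) thr

  lens <- nchar(derep$sequence)
  L <- max(lens)
  padded <- paste0(derep$sequence,
                   strrep("-", L - lens))
  mat <- matrix(match(unlist(strsplit(padded, "", fixed = TRUE)),
                      MED_SYMBOLS),
                nrow = n, ncol = L, byrow = TRUE)
  w <- as.numeric(derep$abundance)

  clusters <- list()
  decompose <- function(rows) {
    ent <- .column_entropies(mat, rows, w)
    jmax <- which.max(ent)
    if (ent[jmax] > thr_fun(sum(w[rows]))) {
      for (sym in unique(mat[rows, jmax])) {
        decompose(rows[mat[rows, jmax] == sym])
      }
    } else {
      clusters[[length(clusters) + 1L]] <<- rows
    }
  }
  decompose(seq_len(n))

  keep <- vapply(clusters, function(rows) sum(w[rows]) >= floor_reads,
                 logical(1))
  clusters <- clusters[keep]
  assign <- rep(NA_integer_, n)
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  ## representative: most abundant member = lowest derep index
  feats <- vapply(clusters, function(rows) derep$sequence[min(rows)],
                  character(1))
  out <- table_from_assignment(derep, assign, features = feats,
                               method = "med", scope = "pooled")
  attr(out, "n_clusters_floored") <- sum(!keep)
  out
}
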