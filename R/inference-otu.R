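#' OTU clustering parameters
#'
#' @param radius similarity radius as a fraction (default 0.03, i.e. 97%
#'   identity).
#' @param strict_prefilter stringent expected-error prefilter before
#'   clustering (UPARSE-style); applied by the pipeline, recorded here.
#' @param strict_max_ee expected-error cap used when `strict_prefilter` is
#'   on.
#' @param inline_chimera_check screen would-be seeds as bimeras of existing
#'   seeds (UPARSE-style).
#' @return an object of class `otu_params`.
#' @export
otu_params <- function(radius = 0.03, strict_prefilter = FALSE,
                       strict_max_ee = 1.0, inline_chimera_check = FALSE) {
  stopifnot(radius >= 0, radius < 1)
  structure(
    list(radius = radius, strict_prefilter = strict_prefilter,
         strict_max_ee = strict_max_ee,
         inline_chimera_check = inline_chimera_check),
    class = "otu_params"
  )
}

## shared greedy clustering loop; returns assignment of derep entries to
## seed indices (NA = discarded as inline chimera)
.greedy_cluster <- function(derep, p) {
  n <- length(derep$sequence)
  assign <- rep(NA_integer_, n)
  seeds <- integer(0)          # indices into derep
  if (n == 0) return(list(assign = assign, seeds = seeds))
  maxlen <- max(nchar(derep$sequence))
  kmax <- max(1L, as.integer(ceiling(p$radius * maxlen)))
  for (i in seq_len(n)) {
    s <- derep$sequence[i]
    hit <- NA_integer_
    if (length(seeds)) {
      d <- seq_dist_matrix(s, derep$sequence[seeds], kmax)[1, ]
      alen <- pmax(nchar(s), nchar(derep$sequence[seeds]))
      ok <- which(d <= p$radius * alen)
      if (length(ok)) hit <- ok[1]   # seeds stored in abundance order
    }
    if (!is.na(hit)) {
      assign[i] <- hit
    } else {
      if (p$inline_chimera_check && length(seeds) >= 2) {
        par <- derep$abundance[seeds] >= 2 * derep$abundance[i]
        if (sum(par) >= 2 &&
            is_bimera(s, derep$sequence[seeds[par]])) {
          next  # discarded, never seeded
        }
      }
      seeds <- c(seeds, i)
      assign[i] <- length(seeds)
    }
  }
  list(assign = assign, seeds = seeds)
}

#' Greedy abundance-sorted OTU clustering
#'
#' Iterates over the dereplicated set in decreasing abundance; each sequence
#' joins the first (most abundant) existing seed whose identity
#' `1 - d / alignment_length` is at least `1 - radius` (Levenshtein
#' distance, alignment length = longer sequence), and otherwise becomes a
#' new seed. Feature sequences are the seeds.
#'
#' @param derep a `derep` set (abundance-ordered).
#' @param p an `otu_params`.
#' @return a `feature_table` (method `"uclust"`).
#' @export
cluster_greedy_otu <- function(derep, p = otu_params()) {
  cl <- .greedy_cluster(derep, p)
  table_from_assignment(derep, cl$assign,
                        features = derep$sequence[cl$seeds],
                        method = "uclust", scope = "pooled")
}

#' Greedy OTU clustering with inline chimera removal
#'
#' As [cluster_greedy_otu()], but a sequence about to become a new seed is
#' first tested as an exact two-parent crossover of existing seeds with at
#' least twice its abundance; such candidates are discarded, never seeded.
#' The stringent quality prefilter that belongs to this strategy is applied
#' upstream by the pipeline (see [otu_params()]).
#'
#' @inheritParams cluster_greedy_otu
#' @return a `feature_table` (method `"uparse"`).
#' @export
cluster_uparse <- function(derep, p = otu_params(strict_prefilter = TRUE,
                                                 inline_chimera_check = TRUE)) {
  p$inline_chimera_check <- TRUE
  cl <- .greedy_cluster(derep, p)
  tab <- table_from_assignment(derep, cl$assign,
                               features = derep$sequence[cl$seeds],
                               method = "uparse", scope = "pooled")
  attr(tab, "n_chimeras_removed") <- sum(is.na(cl$assign))
  tab
}
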