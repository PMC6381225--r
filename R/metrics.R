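#' Recall as a rounded percentage
#'
#' Proportion of expected community members detected, rounded half away
#' from zero to an integer percent. A strain counts as detected if any of
#' its alleles is matched, so the detected count is capped at the expected
#' strain count.
#'
#' @param detected number of strains detected.
#' @param expected number of strains expected (> 0).
#' @return integer percent.
#' @export
recall_pct <- function(detected, expected) {
  stopifnot(expected > 0, detected >= 0)
  round_half_up(100 * min(detected, expected) / expected)
}

#' Count detected strains from classification results
#'
#' @param classified a `classified_features` data.frame.
#' @param refs the `reference_set` classified against.
#' @return list with `strains_detected`, `strains_expected`,
#'   `alleles_detected`, `alleles_expected`, and `recall` (integer
#'   percent at strain level).
#' @export
strain_recall <- function(classified, refs) {
  al <- reference_alleles(refs)
  hit <- classified$category == "Reference"
  matched <- al[match(classified$matched_id[hit], al$template_id), ]
  det <- length(unique(matched$strain_id))
  list(strains_detected = det,
       strains_expected = length(refs$strain_id),
       alleles_detected = length(unique(matched$template_id)),
       alleles_expected = nrow(al),
       recall = recall_pct(det, length(refs$strain_id)))
}

#' Overall precision: all non-Reference features are false positives
#'
#' @param counts named category counts from [category_counts()] (or any
#'   vector with `Reference` and `total` entries).
#' @return integer percent, `100 * Reference / total` rounded half up.
#' @export
overall_precision <- function(counts) {
  if (counts[["total"]] == 0) return(NA_real_)
  round_half_up(100 * counts[["Reference"]] / counts[["total"]])
}

#' Technical precision: only Ref Noisy features are false positives
#'
#' Counts only sequencer-noise satellites against the method; contaminants
#' are genuinely present DNA, so they are excluded from the denominator.
#'
#' @param counts named category counts with `Reference` and `RefNoisy`.
#' @return integer percent, `100 * Reference / (Reference + RefNoisy)`
#'   rounded half up; NA if both are zero.
#' @export
technical_precision <- function(counts) {
  den <- counts[["Reference"]] + counts[["RefNoisy"]]
  if (den == 0) return(NA_real_)
  round_half_up(100 * counts[["Reference"]] / den)
}

#' Percentage of reads mapped to Reference features
#'
#' @param classified a `classified_features` data.frame.
#' @param sample optional sample name; default all samples.
#' @return percent with one decimal.
#' @export
reference_read_fraction <- function(classified, sample = NULL) {
  fr <- category_read_fractions(classified, sample)
  round_half_up(100 * fr[["Reference"]], 1)
}

#' Shannon diversity index
#'
#' `H = -sum p ln p` (natural log) over renormalized proportions.
#'
#' @param x abundances or proportions.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Inverse Simpson diversity index
#'
#' `D2 = 1 / sum p^2` over renormalized proportions.
#'
#' @inheritParams shannon_index
#' @return inverse Simpson index.
#' @export
inv_simpson <- function(x) {
  p <- x[x > 0] / sum(x)
  1 / sum(p^2)
}

#' Fisher's log-series alpha
#'
#' The unique `alpha > 0` solving `S = alpha * ln(1 + N / alpha)` for `S`
#' observed features among `N` reads, found by bracketed root-finding to
#' within 1e-9. Undefined (error) for `S < 2` or `S >= N`.
#'
#' @param S number of observed features.
#' @param N number of reads.
#' @return Fisher's alpha.
#' @export
fisher_alpha <- function(S, N) {
  if (S <= 1) stop("log-series fit needs at least two species")
  if (S >= N) stop("Fisher's alpha diverges for S >= N")
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-12
  hi <- max(S, 1)
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Alpha diversity triple of a count vector
#'
#' @param x feature abundances.
#' @return named vector `shannon`, `inv_simpson`, `fisher` (the latter NA
#'   where undefined).
#' @export
alpha_diversity <- function(x) {
  x <- x[x > 0]
  S <- length(x)
  N <- sum(x)
  fish <- tryCatch(fisher_alpha(S, N), error = function(e) NA_real_)
  c(shannon = shannon_index(x), inv_simpson = inv_simpson(x), fisher = fish)
}

#' Expected alpha diversity from design proportions
#'
#' Indices computed on the known strain proportions of the community
#' design; the Fisher index additionally needs a read total.
#'
#' @param proportions strain genomic proportions.
#' @param n_reads read count for the Fisher index (NA if omitted).
#' @return named vector as [alpha_diversity()].
#' @export
expected_alpha <- function(proportions, n_reads = NULL) {
  p <- proportions[proportions > 0]
  S <- length(p)
  fish <- if (is.null(n_reads)) NA_real_ else {
    tryCatch(fisher_alpha(S, n_reads), error = function(e) NA_real_)
  }
  c(shannon = shannon_index(p), inv_simpson = inv_simpson(p), fisher = fish)
}

#' Depth-normalized feature total
#'
#' Default computes `total * sample_reads / median_reads`. Note that this
#' multiplies by depth, which amplifies rather than corrects depth
#' differences; `invert = TRUE` computes `total * median_reads /
#' sample_reads` instead. Both are provided deliberately — see the methods
#' vignette for why the default is the printed-convention form.
#'
#' @param total feature total of the sample.
#' @param sample_reads output reads of the sample.
#' @param median_reads median output reads across samples.
#' @param invert use the depth-correcting form.
#' @return normalized total.
#' @export
normalized_feature_total <- function(total, sample_reads, median_reads,
                                     invert = FALSE) {
  if (invert) total * median_reads / sample_reads
  else total * sample_reads / median_reads
}

#' Signal and noise abundance summaries
#'
#' Splits features into signal (Reference) and noise (everything else),
#' excluding zero-abundance features, and summarizes log10 abundances.
#' The overlap statistic is `min(signal) - Q3(noise)` on the log10 scale:
#' positive values mean the weakest community member still sits above the
#' bulk of the noise.
#'
#' @param classified a `classified_features` data.frame.
#' @param sample optional sample name; default total abundances.
#' @return list with `signal` and `noise` (`median`, `iqr`, `n` each, on
#'   log10 abundance) and `overlap` (NA when either group is empty).
#' @export
signal_noise_summary <- function(classified, sample = NULL) {
  ab <- if (is.null(sample)) classified$abundance else classified[[sample]]
  grp_summary <- function(v) {
    v <- v[v > 0]
    if (!length(v)) return(list(median = NA_real_, iqr = NA_real_, n = 0L))
    lv <- log10(v)
    list(median = median(lv), iqr = unname(diff(quantile(lv, c(.25, .75)))),
         n = length(v))
  }
  sig <- ab[classified$category == "Reference"]
  noi <- ab[classified$category != "Reference"]
  s <- grp_summary(sig)
  n <- grp_summary(noi)
  overlap <- if (s$n == 0 || n$n == 0) NA_real_ else {
    min(log10(sig[sig > 0])) - unname(quantile(log10(noi[noi > 0]), 0.75))
  }
  list(signal = s, noise = n, overlap = overlap)
}

#' Per-sample metrics report for one classified feature table
#'
#' @param classified a `classified_features` data.frame.
#' @param refs the `reference_set` used for classification.
#' @return data.frame, one row per sample, with recall, both precisions,
#'   reference read fraction, category counts and alpha diversity.
#' @export
metrics_report <- function(classified, refs) {
  samples <- attr(classified, "samples")
  rows <- lapply(samples, function(s) {
    ab <- classified[[s]]
    present <- ab > 0
    cl_s <- classified[present, , drop = FALSE]
    attr(cl_s, "samples") <- samples
    class(cl_s) <- class(classified)
    counts <- category_counts(cl_s)
    al <- reference_alleles(refs)
    hit <- cl_s$category == "Reference"
    det <- length(unique(al$strain_id[match(cl_s$matched_id[hit],
                                            al$template_id)]))
    alpha <- alpha_diversity(ab[present])
    data.frame(
      sample = s, method = attr(classified, "method"),
      total_features = counts[["total"]],
      reference = counts[["Reference"]], ref_noisy = counts[["RefNoisy"]],
      contaminant = counts[["Contaminant"]],
      contam_noisy = counts[["ContamNoisy"]], other = counts[["Other"]],
      recall = recall_pct(det, length(refs$strain_id)),
      overall_precision = overall_precision(counts),
      technical_precision = technical_precision(counts),
      reference_read_pct = reference_read_fraction(cl_s, s),
      shannon = alpha[["shannon"]], inv_simpson = alpha[["inv_simpson"]],
      fisher = alpha[["fisher"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
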