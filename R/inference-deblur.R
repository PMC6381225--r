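#' Deblur-style denoising parameters
#'
#' @param error_profile expected error frequencies at Hamming distances
#'   1..11 from a template. No canonical values exist for a simulated
#'   instrument, so the default is a plausibly decaying profile; treat it as
#'   configuration, not a measured property.
#' @param trim_len optional common length to which all sequences must
#'   conform (checked, not applied; trimming belongs to preprocessing).
#' @return an object of class `deblur_params`.
#' @export
deblur_params <- function(error_profile = c(0.06, 0.02, 0.02, 0.01, 0.005,
                                            0.005, 0.005, 0.001, 0.001,
                                            0.001, 0.0005),
                          trim_len = NULL) {
  stopifnot(length(error_profile) == 11, all(error_profile >= 0),
            all(error_profile < 1), all(diff(error_profile) <= 1e-12))
  structure(list(error_profile = error_profile, trim_len = trim_len),
            class = "deblur_params")
}

#' Deblur-style error subtraction
#'
#' Requires equal-length sequences (positional error model). In decreasing
#' abundance order, each sequence's expected error reads
#' `a * error_profile[d]` are subtracted from the (current) abundances of
#' all neighbors at Hamming distance `d <= 11`, where `a` is the current
#' sequence's current abundance. Sequences whose abundance remains above
#' zero after all subtractions are the inferred features, carrying their
#' residual abundances (per-sample counts are scaled proportionally).
#'
#' @param derep a `derep` set (abundance-ordered).
#' @param p a `deblur_params`.
#' @return a `feature_table` (method `"deblur"`).
#' @export
denoise_deblur <- function(derep, p = deblur_params()) {
  n <- length(derep$sequence)
  empty_counts <- matrix(integer(0), nrow = 0, ncol = ncol(derep$counts),
                         dimnames = list(NULL, colnames(derep$counts)))
  if (n == 0) {
    return(feature_table(character(0), empty_counts, "deblur", "pooled"))
  }
  lens <- unique(nchar(derep$sequence))
  if (length(lens) != 1) {
    stop("deblur-style denoising requires equal-length sequences; got ",
         length(lens), " distinct lengths")
  }
  if (!is.null(p$trim_len) && lens != p$trim_len) {
    stop("sequences are not at trim_len = ", p$trim_len)
  }
  residual <- as.numeric(derep$abundance)
  if (any(p$error_profile > 0)) {
    for (i in seq_len(n)) {
      if (residual[i] <= 0) next
      d <- .hamming_bounded_matrix(derep$sequence[i], derep$sequence, 11L)[1, ]
      nb <- which(d >= 1L & d <= 11L)
      if (length(nb)) {
        residual[nb] <- residual[nb] - residual[i] * p$error_profile[d[nb]]
      }
    }
  }
  keep <- which(residual > 0)
  if (!length(keep)) {
    return(feature_table(character(0), empty_counts, "deblur", "pooled"))
  }
  scale <- residual[keep] / derep$abundance[keep]
  counts <- round(derep$counts[keep, , drop = FALSE] * scale)
  storage.mode(counts) <- "integer"
  out <- feature_table(derep$sequence[keep], counts, "deblur", "pooled")
  attr(out, "residual") <- setNames(residual[keep], derep$sequence[keep])
  out
}
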