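#' Describe a serial dilution design
#'
#' A `fold`-fold serial dilution of one template extraction across
#' `n_samples` samples: sample k (1-based) has relative template
#' concentration `fold^-(k-1)`. A fixed-mass contaminant pool is added to
#' every sample, so the contaminant share of total DNA grows as the template
#' mass shrinks. Defaults mirror a 9-sample 3-fold series ending at 1/6561.
#'
#' @param n_samples number of samples (>= 1).
#' @param fold dilution factor (> 1; the degenerate value 1 is allowed for
#'   constant-concentration checks).
#' @param template_mass0 template mass of the undiluted sample (> 0).
#' @param contaminant_mass contaminant pool mass added per sample (>= 0).
#' @param depth_per_sample integer read depth per sample (recycled).
#' @return an object of class `dilution_design`.
#' @export
dilution_design <- function(n_samples = 9, fold = 3, template_mass0 = 1,
                            contaminant_mass = 0.001,
                            depth_per_sample = 10000L) {
  stopifnot(n_samples >= 1, fold >= 1, template_mass0 > 0,
            contaminant_mass >= 0)
  structure(
    list(n_samples = as.integer(n_samples), fold = fold,
         template_mass0 = template_mass0,
         contaminant_mass = contaminant_mass,
         depth_per_sample = rep_len(as.integer(depth_per_sample), n_samples)),
    class = "dilution_design"
  )
}

#' Relative template concentration of a dilution sample
#'
#' @param design a `dilution_design`.
#' @param k sample index (1-based).
#' @return `fold^-(k-1)`.
#' @export
relative_concentration <- function(design, k) {
  stopifnot(all(k >= 1), all(k <= design$n_samples))
  design$fold^-(k - 1)
}

#' Expected contaminant read fraction at dilution step k
#'
#' Closed form `C / (C + T * fold^-(k-1))` with `C` the contaminant mass and
#' `T` the undiluted template mass; strictly increasing in `k` whenever
#' `C > 0` and `fold > 1`.
#'
#' @inheritParams relative_concentration
#' @return numeric vector of expected contaminant fractions.
#' @export
expected_contaminant_fraction <- function(design, k) {
  conc <- relative_concentration(design, k)
  C <- design$contaminant_mass
  T0 <- design$template_mass0
  if (C == 0) return(rep(0, length(k)))
  C / (C + T0 * conc)
}

#' Compose the template mixture of one dilution sample
#'
#' Returns the expected read fraction of every template (reference alleles
#' and contaminants) in sample `k`. The contaminant group receives mass
#' `C / (C + T * fold^-(k-1))`; within groups, fractions are proportional to
#' genomic proportion (split evenly across a strain's alleles) or relative
#' mass. Optional per-template amplification bias multipliers are applied
#' before renormalization.
#'
#' @inheritParams relative_concentration
#' @param refs a `reference_set`.
#' @param contam a `contaminant_pool` (or NULL for none).
#' @param bias named numeric vector of amplification multipliers by
#'   template id; missing templates default to 1.
#' @return named numeric vector of expected fractions summing to 1, with
#'   attribute `origin_class` ("reference" or "contaminant" per template).
#' @export
compose_sample <- function(refs, contam, design, k, bias = NULL) {
  stopifnot(inherits(refs, "reference_set"), k >= 1, k <= design$n_samples)
  fc <- if (is.null(contam) || length(contam$contam_id) == 0 ||
            design$contaminant_mass == 0) 0
        else expected_contaminant_fraction(design, k)
  if (design$template_mass0 == 0 && design$contaminant_mass == 0) {
    stop("empty sample: no template and no contaminant mass")
  }
  al <- reference_alleles(refs)
  n_all <- lengths(refs$alleles)
  per_allele <- rep(refs$genomic_proportion / n_all, n_all)
  frac <- setNames((1 - fc) * per_allele, al$template_id)
  cls <- setNames(rep("reference", nrow(al)), al$template_id)
  if (fc > 0) {
    cf <- setNames(fc * contam$relative_mass, contam$contam_id)
    frac <- c(frac, cf)
    cls <- c(cls, setNames(rep("contaminant", length(cf)), contam$contam_id))
  }
  if (!is.null(bias)) {
    mult <- rep(1, length(frac))
    names(mult) <- names(frac)
    hit <- intersect(names(bias), names(frac))
    mult[hit] <- bias[hit]
    frac <- frac * mult
  }
  frac <- frac / sum(frac)
  attr(frac, "origin_class") <- cls
  frac
}
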