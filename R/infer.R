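#' Method registry
#'
#' The six inference strategies implemented by the package.
#'
#' @return character vector of method names.
#' @export
inference_methods <- function() {
  c("uclust", "uparse", "unoise", "deblur", "dada", "med")
}

## default parameter object per method
default_method_params <- function(method) {
  switch(method,
    uclust = otu_params(),
    uparse = otu_params(strict_prefilter = TRUE, inline_chimera_check = TRUE),
    unoise = unoise_params(),
    deblur = deblur_params(),
    dada = dada_params(),
    med = med_params(),
    stop("unknown method: ", method)
  )
}

## run one method on one derep; chimera placement per method convention
.run_method <- function(method, derep, params, total_reads = NULL) {
  if (method == "uclust") {
    ## separate pre-clustering chimera screen on unique reads
    flags <- flag_bimeras(derep$sequence, derep$abundance)
    tab <- cluster_greedy_otu(derep_subset(derep, which(!flags)), params)
    attr(tab, "n_chimeras_removed") <- sum(flags)
    tab
  } else if (method == "uparse") {
    cluster_uparse(derep, params)                   # inline chimera check
  } else if (method == "unoise") {
    remove_chimeras(denoise_unoise(derep, params))  # post-inference
  } else if (method == "deblur") {
    remove_chimeras(denoise_deblur(derep, params))  # post-inference
  } else if (method == "dada") {
    remove_chimeras(denoise_dada(derep, params))    # post-inference
  } else if (method == "med") {
    remove_chimeras(decompose_med(derep, params, total_reads = total_reads))
  } else {
    stop("unknown method: ", method)
  }
}

#' Infer features with one method, per sample or pooled
#'
#' Front door to the six inference strategies. Per-sample scope runs the
#' method independently on each sample's dereplicated reads and unions the
#' resulting features; pooled scope runs it once on the pooled
#' dereplication. DADA-style denoising processes samples individually in
#' both scopes (that is its defining reproducibility property), and the
#' entropy decomposition's abundance floor is taken relative to the reads
#' actually processed together, which is what couples its results to scope.
#'
#' @param samples named list of `merged_reads` (one per sample), or a
#'   single `merged_reads` data.frame.
#' @param method one of [inference_methods()].
#' @param params method parameter object; defaults per method.
#' @param scope `"per-sample"` or `"pooled"`.
#' @return a `feature_table` with per-sample counts.
#' @export
infer_features <- function(samples, method = inference_methods(),
                           params = NULL, scope = c("per-sample", "pooled")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (is.data.frame(samples)) samples <- list(sample_1 = samples)
  if (is.null(params)) params <- default_method_params(method)

  effective_scope <- if (method == "dada") "per-sample" else scope
  if (effective_scope == "pooled") {
    derep <- dereplicate(samples)
    tab <- .run_method(method, derep, params,
                       total_reads = sum(derep$abundance))
    tab$scope <- scope
    return(tab)
  }
  ## per-sample: run independently, then union features
  tabs <- lapply(names(samples), function(s) {
    d <- dereplicate(samples[[s]], sample = s)
    .run_method(method, d, params, total_reads = sum(d$abundance))
  })
  feats <- unique(unlist(lapply(tabs, function(t) t$sequence)))
  counts <- matrix(0L, nrow = length(feats), ncol = length(samples),
                   dimnames = list(NULL, names(samples)))
  for (i in seq_along(tabs)) {
    m <- match(tabs[[i]]$sequence, feats)
    counts[m, i] <- as.integer(tabs[[i]]$abundance)
  }
  out <- feature_table(feats, counts, method, scope)
  attr(out, "per_sample_tables") <- setNames(tabs, names(samples))
  out
}
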