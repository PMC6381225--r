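## default configuration tree; run_config() validates against these keys
.config_defaults <- function() {
  list(
    seed = 1L,
    community = list(n_strains = 8L, amplicon_len = 253L,
                     min_pairwise_dist = 20L, allele_spec = 1L,
                     proportions = NULL),
    contaminants = list(n = 30L, total_mass = 0.001, mass_sdlog = 1,
                        min_dist = 20L),
    design = list(n_samples = 9L, fold = 3, template_mass0 = 1,
                  depth_per_sample = 10000L),
    error = list(read_len = 251L, mean_q_fwd = c(38, 30),
                 mean_q_rev = c(37, 25), sd_q = 3, chimera_rate = 0.005),
    preprocess = list(head_trim = 15L, trim_fwd = 230L, trim_rev = 210L,
                      max_merge_diffs = 10L, min_overlap = 16L,
                      length_window = c(220L, 225L),
                      max_expected_errors_merged = 2,
                      max_ee_fwd = 2.5, max_ee_rev = 2.5),
    methods = inference_methods(),
    scope = "per-sample",
    classify = list(max_noisy_dist = 10L,
                    require_lower_abundance_for_noisy = TRUE),
    method_params = list()
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      .merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Build a validated run configuration
#'
#' Nested configuration for the end-to-end pipeline with a strict schema:
#' unknown keys are rejected before any stage runs. All method defaults
#' (alpha = 2, omega = 1e-40, 3% radius, 0.02% floor, 10 merge differences,
#' expected-error caps 2 / 2.5 / 2.5, 10-nt noisy radius) live in the
#' parameter constructors and can be overridden under `method_params`.
#'
#' @param ... named overrides of the default tree (see
#'   `ampbench:::.config_defaults()` for the shape), e.g.
#'   `design = list(n_samples = 3)`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- .merge_config(.config_defaults(), user)
  stopifnot(cfg$scope %in% c("per-sample", "pooled"))
  cfg$methods <- match.arg(cfg$methods, inference_methods(),
                           several.ok = TRUE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys follow [run_config()].
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

## method -> preprocessing branch and mapping radius
.method_branch <- function(method) if (method == "dada") "dada" else "merged"
.method_map_radius <- function(method) {
  if (method %in% c("uclust", "uparse")) 0.03 else 0
}

## build method params from config overrides
.method_params_from_config <- function(config, method) {
  p <- default_method_params(method)
  ov <- config$method_params[[method]]
  if (!is.null(ov)) {
    for (k in names(ov)) {
      if (!k %in% names(p)) stop("unknown ", method, " parameter: ", k)
      p[[k]] <- ov[[k]]
    }
  }
  p
}

## simulate + preprocess; shared by run_all and compare_scopes
.prepare_inputs <- function(config) {
  refs <- generate_reference_set(
    config$community$n_strains, config$community$amplicon_len,
    config$community$min_pairwise_dist, config$community$allele_spec,
    genomic_proportion = config$community$proportions,
    seed = derive_seed(config$seed, 101L))
  contam <- if (config$contaminants$n > 0) {
    generate_contaminant_pool(
      config$contaminants$n, config$community$amplicon_len, refs,
      min_dist = config$contaminants$min_dist,
      total_mass = config$contaminants$total_mass,
      mass_sdlog = config$contaminants$mass_sdlog,
      seed = derive_seed(config$seed, 102L))
  } else NULL
  design <- dilution_design(config$design$n_samples, config$design$fold,
                            config$design$template_mass0,
                            contaminant_mass = if (is.null(contam)) 0 else
                              config$contaminants$total_mass,
                            depth_per_sample = config$design$depth_per_sample)
  model <- do.call(error_model, config$error)
  sim <- simulate_dilution_series(refs, contam, design, model,
                                  seed = derive_seed(config$seed, 103L))
  pp <- do.call(preprocess_params, config$preprocess)
  merged <- lapply(sim, preprocess_sample, params = pp, branch = "merged")
  dada_branch <- lapply(sim, preprocess_sample, params = pp, branch = "dada")
  pre_ledger <- do.call(rbind, lapply(names(merged), function(s) {
    data.frame(sample = s, t(attr(merged[[s]], "ledger")))
  }))
  ## community restricted to the merged-read window for exact-match
  ## classification
  win_start <- config$preprocess$head_trim + 1L
  win_end <- config$community$amplicon_len - config$preprocess$head_trim
  refs_win <- window_community(refs, win_start, win_end)
  contam_win <- if (is.null(contam)) NULL else
    window_community(contam, win_start, win_end)
  list(refs = refs, contam = contam, refs_win = refs_win,
       contam_win = contam_win, design = design, model = model,
       sim = sim, merged = merged, dada_branch = dada_branch,
       params = pp, pre_ledger = pre_ledger)
}

## records feeding one method (branch + optional strict prefilter)
.method_records <- function(inputs, config, method) {
  recs <- if (.method_branch(method) == "dada") inputs$dada_branch
          else inputs$merged
  if (method == "uparse") {
    p <- .method_params_from_config(config, method)
    if (isTRUE(p$strict_prefilter)) {
      recs <- lapply(recs, expected_error_filter, max_ee = p$strict_max_ee)
    }
  }
  recs
}

#' Run the full benchmark pipeline
#'
#' simulate -> preprocess -> infer -> map -> classify -> metrics, for every
#' configured method, fully deterministic for a fixed config and seed
#' (per-stage seeds are derived from the run seed). Optionally writes all
#' stage artifacts (FASTQ, FASTA, TSV tables, report, ledger) to `outdir`.
#'
#' @param config a `run_config`.
#' @param outdir optional artifact directory.
#' @param write_fastq also write simulated FASTQ (large); only with
#'   `outdir`.
#' @return list with elements `refs`, `contam`, `design`, `samples`
#'   (simulated reads), `preprocessed`, `tables` (mapped feature tables by
#'   method), `classified` (by method), `report` (one row per sample x
#'   method), `trends` (dilution trend table), `ledger`, `config`.
#' @export
run_all <- function(config = run_config(), outdir = NULL,
                    write_fastq = FALSE) {
  inputs <- .prepare_inputs(config)
  cl_p <- do.call(classify_params, config$classify)

  tables <- list()
  classified <- list()
  reports <- list()
  method_ledger <- list()
  for (method in config$methods) {
    recs <- .method_records(inputs, config, method)
    p <- .method_params_from_config(config, method)
    tab <- infer_features(recs, method, params = p, scope = config$scope)
    mapped <- map_reads_to_features(recs, tab,
                                    max_dist_frac = .method_map_radius(method))
    cl <- classify_features(mapped, inputs$refs_win, inputs$contam_win, cl_p)
    tables[[method]] <- mapped
    classified[[method]] <- cl
    reports[[method]] <- metrics_report(cl, inputs$refs_win)
    method_ledger[[method]] <- data.frame(
      method = method, n_features = n_features(mapped),
      unmapped_reads = sum(attr(mapped, "unmapped")),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  trends <- dilution_trends(classified, inputs$design)
  ledger <- list(preprocess = inputs$pre_ledger,
                 methods = do.call(rbind, method_ledger),
                 seed = config$seed)

  out <- list(refs = inputs$refs, contam = inputs$contam,
              design = inputs$design, samples = inputs$sim,
              preprocessed = inputs$merged, tables = tables,
              classified = classified, report = report, trends = trends,
              ledger = ledger, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_community_fasta(inputs$refs, file.path(outdir, "references.fasta"))
    if (!is.null(inputs$contam)) {
      write_community_fasta(inputs$contam,
                            file.path(outdir, "contaminants.fasta"))
    }
    if (write_fastq) {
      for (s in names(inputs$sim)) {
        write_sample_fastq(inputs$sim[[s]], outdir, s)
      }
    }
    for (method in names(tables)) {
      write_feature_table(tables[[method]],
                          file.path(outdir, paste0(method, "_features.fasta")),
                          file.path(outdir, paste0(method, "_features.tsv")))
      write_classification(classified[[method]],
                           file.path(outdir, paste0(method, "_classified.tsv")))
    }
    write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(trends, file.path(outdir, "trends.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ledger$preprocess, file.path(outdir, "ledger_preprocess.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ledger$methods, file.path(outdir, "ledger_methods.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Dilution-axis trend table
#'
#' Per method and dilution step: per-category feature counts (features with
#' nonzero reads in that sample) and the signal/noise median log-abundance
#' gap, plus the Spearman correlation of Contaminant-feature counts with
#' the dilution step.
#'
#' @param classified named list of `classified_features`, one per method.
#' @param design the `dilution_design` behind the samples.
#' @return data.frame with attribute `spearman` (named vector per method).
#' @export
dilution_trends <- function(classified, design) {
  rows <- list()
  rho <- c()
  for (method in names(classified)) {
    cl <- classified[[method]]
    samples <- attr(cl, "samples")
    per_k <- lapply(seq_along(samples), function(k) {
      s <- samples[k]
      present <- cl[[s]] > 0
      cl_s <- cl[present, , drop = FALSE]
      attr(cl_s, "samples") <- samples
      class(cl_s) <- class(cl)
      counts <- category_counts(cl_s)
      sn <- signal_noise_summary(cl_s, s)
      gap <- if (sn$signal$n > 0 && sn$noise$n > 0) {
        sn$signal$median - sn$noise$median
      } else NA_real_
      data.frame(method = method, k = k, sample = s,
                 relative_concentration = relative_concentration(design, k),
                 total_features = counts[["total"]],
                 reference = counts[["Reference"]],
                 ref_noisy = counts[["RefNoisy"]],
                 contaminant = counts[["Contaminant"]],
                 contam_noisy = counts[["ContamNoisy"]],
                 other = counts[["Other"]],
                 signal_noise_gap = gap,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_k)
    rho[method] <- suppressWarnings(
      cor(df$k, df$contaminant, method = "spearman"))
    rows[[method]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spearman") <- rho
  out
}

#' Compare pooled and per-sample processing
#'
#' Runs every configured method under both scopes on identical preprocessed
#' reads and reports, per sample x method, the feature totals and
#' per-category deltas (pooled minus per-sample). DADA-style denoising
#' processes samples individually under both scopes, so its deltas are zero
#' by construction.
#'
#' @param config a `run_config`.
#' @return data.frame of totals and per-category deltas, with attribute
#'   `tables` holding both mapped feature tables per method.
#' @export
compare_scopes <- function(config = run_config()) {
  inputs <- .prepare_inputs(config)
  cl_p <- do.call(classify_params, config$classify)
  rows <- list()
  tabs <- list()
  for (method in config$methods) {
    recs <- .method_records(inputs, config, method)
    p <- .method_params_from_config(config, method)
    res <- lapply(c("per-sample", "pooled"), function(sc) {
      tab <- infer_features(recs, method, params = p, scope = sc)
      mapped <- map_reads_to_features(recs, tab,
                                      max_dist_frac = .method_map_radius(method))
      classify_features(mapped, inputs$refs_win, inputs$contam_win, cl_p)
    })
    names(res) <- c("per_sample", "pooled")
    tabs[[method]] <- res
    samples <- attr(res$per_sample, "samples")
    for (s in samples) {
      cat_counts <- lapply(res, function(cl) {
        present <- cl[[s]] > 0
        cl_s <- cl[present, , drop = FALSE]
        attr(cl_s, "samples") <- samples
        class(cl_s) <- class(cl)
        category_counts(cl_s)
      })
      delta <- cat_counts$pooled - cat_counts$per_sample
      rows[[paste(method, s)]] <- data.frame(
        method = method, sample = s,
        total_per_sample = cat_counts$per_sample[["total"]],
        total_pooled = cat_counts$pooled[["total"]],
        delta_total = delta[["total"]],
        delta_reference = delta[["Reference"]],
        delta_ref_noisy = delta[["RefNoisy"]],
        delta_contaminant = delta[["Contaminant"]],
        delta_contam_noisy = delta[["ContamNoisy"]],
        delta_other = delta[["Other"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tabs
  out
}
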