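#' Feature classification parameters
#'
#' @param max_noisy_dist Levenshtein radius within which a feature is
#'   considered a noisy satellite of a Reference or Contaminant feature
#'   (default 10 nt).
#' @param require_lower_abundance_for_noisy a Ref Noisy feature must be
#'   strictly less abundant than the Reference feature it shadows
#'   (default TRUE). The contaminant satellite rule carries no abundance
#'   requirement.
#' @param noisy_dist_to measure the Ref Noisy distance against the more
#'   abundant Reference-classified `"feature"` (default) or directly
#'   against the `"reference"` allele set (sensitivity analysis).
#' @return an object of class `classify_params`.
#' @export
classify_params <- function(max_noisy_dist = 10L,
                            require_lower_abundance_for_noisy = TRUE,
                            noisy_dist_to = c("feature", "reference")) {
  stopifnot(max_noisy_dist >= 0)
  structure(list(max_noisy_dist = as.integer(max_noisy_dist),
                 require_lower_abundance_for_noisy =
                   isTRUE(require_lower_abundance_for_noisy),
                 noisy_dist_to = match.arg(noisy_dist_to)),
            class = "classify_params")
}

FEATURE_CATEGORIES <- c("Reference", "RefNoisy", "Contaminant",
                        "ContamNoisy", "Other")

#' Classify inferred features into the five evaluation categories
#'
#' Each feature receives exactly one category, by precedence evaluated in
#' decreasing feature abundance:
#' \enumerate{
#'   \item exact match to any reference allele: `Reference`;
#'   \item within `max_noisy_dist` edits of a more abundant
#'     Reference-classified feature: `RefNoisy` (sequencer-noise satellite);
#'   \item exact match to a contaminant sequence: `Contaminant`;
#'   \item within `max_noisy_dist` edits of any Contaminant-classified
#'     feature: `ContamNoisy`;
#'   \item otherwise `Other`.
#' }
#'
#' @param table a `feature_table`.
#' @param refs a `reference_set` (must be non-empty).
#' @param contamdb a `contaminant_pool` (or NULL for none).
#' @param p a `classify_params`.
#' @return data.frame of class `classified_features`: `feature_id`,
#'   `sequence`, `abundance`, `category`, `matched_id`, `distance`, plus
#'   the per-sample count columns.
#' @export
classify_features <- function(table, refs, contamdb = NULL,
                              p = classify_params()) {
  if (is.null(refs) || length(refs$strain_id) == 0) {
    stop("empty reference set")
  }
  n <- length(table$sequence)
  al <- reference_alleles(refs)
  contam_seqs <- if (is.null(contamdb)) character(0) else contamdb$sequence
  contam_ids <- if (is.null(contamdb)) character(0) else contamdb$contam_id

  category <- rep("Other", n)
  matched_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  kmax <- p$max_noisy_dist

  ## rule 1: exact matches to reference alleles
  m <- match(table$sequence, al$sequence)
  ref_feats <- which(!is.na(m))
  category[ref_feats] <- "Reference"
  matched_id[ref_feats] <- al$template_id[m[ref_feats]]
  distance[ref_feats] <- 0L

  ## rule 2: satellites of Reference-classified features
  for (i in which(category == "Other")) {
    s <- table$sequence[i]
    if (p$noisy_dist_to == "reference") {
      d <- seq_dist_matrix(s, al$sequence, kmax)[1, ]
      if (min(d) <= kmax) {
        category[i] <- "RefNoisy"
        matched_id[i] <- al$template_id[which.min(d)]
        distance[i] <- min(d)
      }
      next
    }
    anchor <- ref_feats
    if (p$require_lower_abundance_for_noisy) {
      anchor <- anchor[table$abundance[anchor] > table$abundance[i]]
    }
    if (length(anchor)) {
      d <- seq_dist_matrix(s, table$sequence[anchor], kmax)[1, ]
      if (min(d) <= kmax) {
        category[i] <- "RefNoisy"
        hit <- anchor[which.min(d)]
        matched_id[i] <- sprintf("feature_%04d", hit)
        distance[i] <- min(d)
      }
    }
  }

  ## rule 3: exact matches to contaminant sequences
  mc <- match(table$sequence, contam_seqs)
  hit_c <- which(!is.na(mc) & category == "Other")
  category[hit_c] <- "Contaminant"
  matched_id[hit_c] <- contam_ids[mc[hit_c]]
  distance[hit_c] <- 0L

  ## rule 4: satellites of Contaminant features, no abundance ordering
  contam_feats <- which(category == "Contaminant")
  if (length(contam_feats)) {
    for (i in which(category == "Other")) {
      d <- seq_dist_matrix(table$sequence[i],
                           table$sequence[contam_feats], kmax)[1, ]
      if (min(d) <= kmax) {
        category[i] <- "ContamNoisy"
        matched_id[i] <- sprintf("feature_%04d", contam_feats[which.min(d)])
        distance[i] <- min(d)
      }
    }
  }

  out <- data.frame(
    feature_id = sprintf("feature_%04d", seq_len(n)),
    sequence = table$sequence,
    abundance = table$abundance,
    category = factor(category, levels = FEATURE_CATEGORIES),
    matched_id = matched_id,
    distance = distance,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(table$counts))
  attr(out, "method") <- table$method
  attr(out, "samples") <- colnames(table$counts)
  class(out) <- c("classified_features", "data.frame")
  out
}

#' Count features per category
#'
#' @param classified a `classified_features` data.frame.
#' @return named integer vector over the five categories plus `total`;
#'   the five categories partition the features.
#' @export
category_counts <- function(classified) {
  tab <- table(classified$category)
  out <- setNames(as.integer(tab[FEATURE_CATEGORIES]), FEATURE_CATEGORIES)
  out[is.na(out)] <- 0L
  c(total = nrow(classified), out)
}

#' Read fraction per category
#'
#' @param classified a `classified_features` data.frame.
#' @param sample optional sample name; default sums over all samples.
#' @return named numeric vector over the five categories, summing to 1.
#' @export
category_read_fractions <- function(classified, sample = NULL) {
  ab <- if (is.null(sample)) classified$abundance else classified[[sample]]
  tot <- sum(ab)
  if (tot == 0) {
    return(setNames(rep(NA_real_, 5), FEATURE_CATEGORIES))
  }
  v <- vapply(FEATURE_CATEGORIES, function(ct) {
    sum(ab[classified$category == ct]) / tot
  }, numeric(1))
  v
}

#' Write classification results as TSV
#'
#' @param classified a `classified_features` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classified, path) {
  write.table(classified, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
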