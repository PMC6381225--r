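#' Construct a feature table
#'
#' The common output container of every inference method: inferred feature
#' sequences by samples, with integer read counts.
#'
#' @param sequence character vector of feature sequences (unique).
#' @param counts integer matrix, features x samples.
#' @param method inference method name.
#' @param scope `"per-sample"` or `"pooled"`.
#' @return an object of class `feature_table`, ordered by decreasing total
#'   abundance (ties broken lexicographically).
#' @export
feature_table <- function(sequence, counts, method = "unknown",
                          scope = "pooled") {
  if (is.null(dim(counts))) {
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(NULL, "sample_1"))
  }
  stopifnot(length(sequence) == nrow(counts), all(counts >= 0))
  if (anyDuplicated(sequence)) stop("duplicate feature sequences")
  ab <- rowSums(counts)
  ord <- order(-ab, sequence)
  structure(
    list(sequence = sequence[ord],
         counts = counts[ord, , drop = FALSE],
         abundance = as.numeric(ab[ord]),
         method = method, scope = scope),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table [", x$method, ", ", x$scope, "]: ",
      length(x$sequence), " features x ", ncol(x$counts), " sample(s), ",
      sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

#' Number of features in a table
#' @param table a `feature_table`.
#' @return integer.
#' @export
n_features <- function(table) length(table$sequence)

## build a feature_table from a derep + an assignment of uniques to
## feature indices (NA = discarded); representative defaults to the most
## abundant member (derep is abundance-ordered, so the first member)
table_from_assignment <- function(derep, assign, features = NULL,
                                  method = "unknown", scope = "pooled") {
  keep <- !is.na(assign)
  if (!any(keep)) {
    counts <- matrix(integer(0), nrow = 0, ncol = ncol(derep$counts),
                     dimnames = list(NULL, colnames(derep$counts)))
    return(feature_table(character(0), counts, method, scope))
  }
  idx <- sort(unique(assign[keep]))
  if (is.null(features)) {
    features <- vapply(idx, function(f) {
      derep$sequence[which(assign == f)[1]]
    }, character(1))
  } else {
    features <- features[idx]
  }
  counts <- t(vapply(idx, function(f) {
    colSums(derep$counts[which(assign == f), , drop = FALSE])
  }, numeric(ncol(derep$counts))))
  if (ncol(derep$counts) == 1) counts <- matrix(counts, ncol = 1)
  colnames(counts) <- colnames(derep$counts)
  storage.mode(counts) <- "integer"
  out <- feature_table(features, counts, method, scope)
  members <- split(derep$sequence[keep],
                   factor(assign[keep], levels = idx))
  names(members) <- features
  attr(out, "members") <- members
  out
}

#' Write a feature table as FASTA and TSV
#'
#' @param table a `feature_table`.
#' @param fasta,tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(table, fasta, tsv) {
  ids <- sprintf("%s_%04d", table$method, seq_along(table$sequence))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(table$sequence, ids)), fasta)
  df <- data.frame(feature_id = ids, sequence = table$sequence,
                   total = as.integer(table$abundance), table$counts,
                   check.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, tsv))
}

#' Map reads to inferred features
#'
#' Assigns each preprocessed read to the nearest feature within
#' `max_dist_frac` of the read length (OTU radius), or exactly
#' (`max_dist_frac = 0`, the ASV convention). Ties go to the more abundant
#' feature. Unmapped reads are counted in the `unmapped` attribute.
#'
#' @param records a `merged_reads` data.frame or named list of them.
#' @param table a `feature_table`.
#' @param max_dist_frac mapping radius as a fraction of alignment length
#'   (0.03 for OTU methods, 0 = exact for ASV methods).
#' @return a `feature_table` with recomputed per-sample counts and attribute
#'   `unmapped` (named integer, reads per sample not mapped).
#' @export
map_reads_to_features <- function(records, table, max_dist_frac = 0) {
  derep <- if (inherits(records, "derep")) records else dereplicate(records)
  nfeat <- length(table$sequence)
  assign <- match(derep$sequence, table$sequence)
  if (max_dist_frac > 0 && nfeat > 0) {
    todo <- which(is.na(assign))
    if (length(todo)) {
      maxlen <- max(nchar(derep$sequence[todo]), nchar(table$sequence))
      kmax <- as.integer(ceiling(max_dist_frac * maxlen))
      d <- seq_dist_matrix(derep$sequence[todo], table$sequence, kmax)
      alen <- outer(nchar(derep$sequence[todo]), nchar(table$sequence), pmax)
      ok <- d <= max_dist_frac * alen
      for (r in seq_along(todo)) {
        cand <- which(ok[r, ])
        if (length(cand)) {
          assign[todo[r]] <- cand[which.min(d[r, cand])]
        }
      }
    }
  }
  keep <- !is.na(assign)
  counts <- matrix(0L, nrow = nfeat, ncol = ncol(derep$counts),
                   dimnames = list(NULL, colnames(derep$counts)))
  if (any(keep)) {
    agg <- rowsum(derep$counts[keep, , drop = FALSE], assign[keep])
    counts[as.integer(rownames(agg)), ] <- as.integer(agg)
  }
  unmapped <- colSums(derep$counts[!keep, , drop = FALSE])
  out <- feature_table(table$sequence, counts, table$method, table$scope)
  attr(out, "unmapped") <- unmapped
  out
}
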