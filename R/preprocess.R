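#' Preprocessing parameters
#'
#' Trim, merge and filter settings for paired 16S reads. Defaults follow the
#' common MiSeq V4 protocol: drop the first 15 cycles of each mate, truncate
#' the forward mate at cycle 230 and the reverse at 210, merge with at most
#' 10 overlap differences, keep merged lengths in a 220-225 window, and
#' discard merged reads with more than 2 expected errors. The `dada` branch
#' instead filters the two mates independently (2.5 expected errors each)
#' before merging.
#'
#' @param head_trim 5' cycles removed from both mates.
#' @param trim_fwd,trim_rev last retained cycle of each mate (before head
#'   trimming is applied).
#' @param max_merge_diffs maximum overlap mismatches tolerated by the merger.
#' @param min_overlap minimum ungapped overlap length.
#' @param length_window inclusive `[min, max]` merged-length window.
#' @param max_expected_errors_merged expected-error cap on merged reads.
#' @param max_ee_fwd,max_ee_rev per-mate expected-error caps for the `dada`
#'   filter ordering.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(head_trim = 15L, trim_fwd = 230L,
                              trim_rev = 210L, max_merge_diffs = 10L,
                              min_overlap = 16L,
                              length_window = c(220L, 225L),
                              max_expected_errors_merged = 2,
                              max_ee_fwd = 2.5, max_ee_rev = 2.5) {
  stopifnot(head_trim >= 0, max_merge_diffs >= 0, min_overlap >= 1,
            length(length_window) == 2,
            length_window[1] <= length_window[2],
            max_expected_errors_merged >= 0, max_ee_fwd >= 0, max_ee_rev >= 0)
  structure(
    list(head_trim = as.integer(head_trim), trim_fwd = as.integer(trim_fwd),
         trim_rev = as.integer(trim_rev),
         max_merge_diffs = as.integer(max_merge_diffs),
         min_overlap = as.integer(min_overlap),
         length_window = as.integer(length_window),
         max_expected_errors_merged = max_expected_errors_merged,
         max_ee_fwd = max_ee_fwd, max_ee_rev = max_ee_rev),
    class = "preprocess_params"
  )
}

#' Trim read pairs
#'
#' Removes the first `head_trim` cycles from both mates and truncates the
#' forward/reverse mates at `trim_fwd`/`trim_rev` (positions on the
#' untrimmed read). Qualities are trimmed in lockstep. Reads whose trim
#' window is empty are dropped and counted.
#'
#' @param pairs a `read_pairs` data.frame.
#' @param params a `preprocess_params`.
#' @return trimmed `read_pairs` with attribute `dropped_trim`.
#' @export
trim_reads <- function(pairs, params) {
  lf <- nchar(pairs$fwd_seq)
  lr <- nchar(pairs$rev_seq)
  from <- params$head_trim + 1L
  to_f <- pmin(params$trim_fwd, lf)
  to_r <- pmin(params$trim_rev, lr)
  keep <- to_f >= from & to_r >= from
  dropped <- sum(!keep)
  out <- pairs[keep, , drop = FALSE]
  out$fwd_seq <- substr(out$fwd_seq, from, to_f[keep])
  out$fwd_qual <- substr(out$fwd_qual, from, to_f[keep])
  out$rev_seq <- substr(out$rev_seq, from, to_r[keep])
  out$rev_qual <- substr(out$rev_qual, from, to_r[keep])
  rownames(out) <- NULL
  attr(out, "dropped_trim") <- dropped
  out
}

#' Merge read pairs by best ungapped overlap
#'
#' For each pair, the overlap maximizing the number of matching bases among
#' admissible overlaps (mismatches <= `max_merge_diffs`, length >=
#' `min_overlap`) is chosen between the forward mate and the reverse
#' complement of the reverse mate. Agreeing overlap bases get posterior
#' error probability `e1 * e2`; disagreeing bases keep the higher-quality
#' base with posterior `e_hi / (e_hi + e_lo)`; posterior Phred values are
#' clamped to [2, 41]. Pairs with no admissible overlap are discarded and
#' counted.
#'
#' @inheritParams trim_reads
#' @return data.frame of class `merged_reads` with columns `read_id`,
#'   `sequence`, `quality`, `origin_id`, `origin_class`, plus attribute
#'   `dropped_merge`.
#' @export
merge_pairs <- function(pairs, params) {
  m <- .merge_pairs_cpp(pairs$fwd_seq, pairs$rev_seq,
                        pairs$fwd_qual, pairs$rev_qual,
                        params$max_merge_diffs, params$min_overlap)
  keep <- m$status == 1L
  out <- data.frame(
    read_id = pairs$read_id[keep],
    sequence = m$sequence[keep],
    quality = m$quality[keep],
    origin_id = pairs$origin_id[keep],
    origin_class = pairs$origin_class[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("merged_reads", "data.frame")
  attr(out, "dropped_merge") <- sum(!keep)
  out
}

#' Filter merged reads by length window
#'
#' @param merged a `merged_reads` data.frame.
#' @param params a `preprocess_params`.
#' @return filtered `merged_reads` with attribute `dropped_length`.
#' @export
length_filter <- function(merged, params) {
  len <- nchar(merged$sequence)
  keep <- len >= params$length_window[1] & len <= params$length_window[2]
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("merged_reads", "data.frame")
  attr(out, "dropped_length") <- sum(!keep)
  out
}

#' Expected errors of quality strings
#'
#' `EE = sum_i 10^(-q_i/10)` over the bases of a read.
#'
#' @param quality character vector of phred+33 quality strings.
#' @return numeric vector of expected errors.
#' @export
expected_errors <- function(quality) {
  if (any(!nzchar(quality))) stop("empty quality string")
  .phred_expected_errors(quality)
}

#' Filter records by maximum expected errors
#'
#' @param records a data.frame with a `quality` column (merged reads) or a
#'   `read_pairs` table when `mate` is given.
#' @param max_ee expected-error cap; records with `EE <= max_ee` are kept.
#' @param mate for paired input, which mate's qualities to filter on
#'   (`"fwd"` or `"rev"`).
#' @return filtered records with attribute `dropped_ee`.
#' @export
expected_error_filter <- function(records, max_ee, mate = NULL) {
  qual <- if (is.null(mate)) records$quality
          else records[[paste0(mate, "_qual")]]
  ee <- expected_errors(qual)
  keep <- ee <= max_ee
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  attr(out, "dropped_ee") <- sum(!keep)
  out
}

#' Dereplicate sequences into unique entries with abundances
#'
#' Exact-sequence grouping with per-sample counts. Entries are ordered by
#' decreasing total abundance, ties broken lexicographically by sequence, so
#' every abundance-sorted algorithm downstream iterates in a reproducible
#' order.
#'
#' @param records a `merged_reads` data.frame, or a named list of them (one
#'   per sample) for pooled dereplication.
#' @param sample name used for single-sample input.
#' @return an object of class `derep`: list with `sequence` (character),
#'   `abundance` (integer), and `counts` (integer matrix, sequences x
#'   samples).
#' @export
dereplicate <- function(records, sample = "sample_1") {
  if (is.data.frame(records)) {
    records <- setNames(list(records), sample)
  }
  seqs <- unlist(lapply(records, function(r) r$sequence), use.names = FALSE)
  samp <- rep(names(records), vapply(records, nrow, integer(1)))
  if (length(seqs) == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = length(records),
                     dimnames = list(NULL, names(records)))
    return(structure(list(sequence = character(0), abundance = integer(0),
                          counts = counts), class = "derep"))
  }
  tab <- table(factor(seqs), factor(samp, levels = names(records)))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  ab <- rowSums(counts)
  ord <- order(-ab, rownames(counts))
  structure(
    list(sequence = rownames(counts)[ord],
         abundance = as.integer(ab[ord]),
         counts = counts[ord, , drop = FALSE]),
    class = "derep"
  )
}

#' @export
print.derep <- function(x, ...) {
  cat("derep:", length(x$sequence), "unique sequences,",
      sum(x$abundance), "reads,", ncol(x$counts), "sample(s)\n")
  invisible(x)
}

## subset a derep while preserving ordering invariants
derep_subset <- function(derep, idx) {
  structure(
    list(sequence = derep$sequence[idx],
         abundance = derep$abundance[idx],
         counts = derep$counts[idx, , drop = FALSE]),
    class = "derep"
  )
}

#' Preprocess one sample end to end
#'
#' Runs trim, merge, length filter and expected-error filter, with a full
#' read-count ledger. Two filter orderings are supported: `"merged"`
#' (filter the merged read at `max_expected_errors_merged`) and `"dada"`
#' (filter the mates independently at `max_ee_fwd`/`max_ee_rev` before
#' merging, as iterative error-model denoisers conventionally do).
#'
#' @param pairs a `read_pairs` data.frame.
#' @param params a `preprocess_params`.
#' @param branch filter ordering, `"merged"` or `"dada"`.
#' @return a `merged_reads` data.frame with attribute `ledger`, a named
#'   integer vector satisfying
#'   `input = output + dropped_trim + dropped_merge + dropped_length + dropped_ee`.
#' @export
preprocess_sample <- function(pairs, params = preprocess_params(),
                              branch = c("merged", "dada")) {
  branch <- match.arg(branch)
  n_in <- nrow(pairs)
  trimmed <- trim_reads(pairs, params)
  d_trim <- attr(trimmed, "dropped_trim")
  if (branch == "dada") {
    f1 <- expected_error_filter(trimmed, params$max_ee_fwd, mate = "fwd")
    f2 <- expected_error_filter(f1, params$max_ee_rev, mate = "rev")
    d_ee <- attr(f1, "dropped_ee") + attr(f2, "dropped_ee")
    merged <- merge_pairs(f2, params)
    d_merge <- attr(merged, "dropped_merge")
    lenf <- length_filter(merged, params)
    d_len <- attr(lenf, "dropped_length")
    out <- lenf
  } else {
    merged <- merge_pairs(trimmed, params)
    d_merge <- attr(merged, "dropped_merge")
    lenf <- length_filter(merged, params)
    d_len <- attr(lenf, "dropped_length")
    out <- expected_error_filter(lenf, params$max_expected_errors_merged)
    d_ee <- attr(out, "dropped_ee")
  }
  ledger <- c(input = n_in, output = nrow(out), dropped_trim = d_trim,
              dropped_merge = d_merge, dropped_length = d_len,
              dropped_ee = d_ee)
  attr(out, "ledger") <- ledger
  out
}

#' Write a dereplicated set as FASTA plus abundance TSV
#'
#' @param derep a `derep` object.
#' @param fasta,tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_derep <- function(derep, fasta, tsv) {
  ids <- sprintf("uniq%06d", seq_along(derep$sequence))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(derep$sequence, ids)), fasta)
  percol <- apply(derep$counts, 1, function(r) {
    paste(paste0(colnames(derep$counts), ":", r), collapse = ",")
  })
  df <- data.frame(sequence = derep$sequence, total = derep$abundance,
                   sample_counts = percol)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, tsv))
}
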