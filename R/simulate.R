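#' Describe the sequencer error model
#'
#' Paired 2 x `read_len` reads with a monotone-decaying mean Phred profile
#' along the cycle, Gaussian jitter, clamping to [2, 41] (Illumina 1.8+
#' convention), per-base quality-dependent substitution errors and an
#' optional PCR bimera rate. The substitution probability defaults to the
#' Phred definition `10^(-q/10)`, split uniformly over the three alternative
#' bases.
#'
#' @param read_len read length in cycles (default 251).
#' @param mean_q_fwd,mean_q_rev length-2 numeric `c(start, end)` mean Phred
#'   at the first and last cycle of each mate; interpolated linearly.
#' @param sd_q Gaussian jitter around the cycle mean.
#' @param substitution_prob function mapping Phred q to per-base
#'   substitution probability; must be non-increasing in q.
#' @param chimera_rate probability that a read derives from a two-parent
#'   crossover (in [0, 1)).
#' @return an object of class `error_model`.
#' @export
error_model <- function(read_len = 251L, mean_q_fwd = c(38, 30),
                        mean_q_rev = c(37, 25), sd_q = 3,
                        substitution_prob = function(q) 10^(-q / 10),
                        chimera_rate = 0) {
  stopifnot(read_len >= 1, chimera_rate >= 0, chimera_rate < 1, sd_q >= 0,
            length(mean_q_fwd) == 2, length(mean_q_rev) == 2)
  qs <- c(2, 10, 20, 30, 41)
  p <- substitution_prob(qs)
  if (any(diff(p) > 1e-12)) {
    stop("substitution_prob must be non-increasing in q")
  }
  structure(
    list(read_len = as.integer(read_len), mean_q_fwd = mean_q_fwd,
         mean_q_rev = mean_q_rev, sd_q = sd_q,
         substitution_prob = substitution_prob, chimera_rate = chimera_rate),
    class = "error_model"
  )
}

## simulate one mate for a block of reads sharing a template
## tint: template as integers 0..3; returns list(seq, qual) char vectors
.simulate_mate <- function(tint, n, q_mean, sd_q, sub_prob) {
  L <- length(tint)
  q <- matrix(round(rep(q_mean, each = n) + rnorm(n * L, 0, sd_q)),
              nrow = n, ncol = L)
  q[q < 2] <- 2L
  q[q > 41] <- 41L
  reads <- matrix(rep(tint, each = n), nrow = n, ncol = L)
  p <- sub_prob(q)
  err <- matrix(runif(n * L) < p, nrow = n, ncol = L)
  ne <- sum(err)
  if (ne > 0) {
    reads[err] <- (reads[err] + sample(1:3, ne, replace = TRUE)) %% 4L
  }
  base_raw <- charToRaw("ACGT")
  seq <- vapply(seq_len(n), function(i) rawToChar(base_raw[reads[i, ] + 1L]),
                character(1))
  qual <- vapply(seq_len(n), function(i) rawToChar(as.raw(q[i, ] + 33L)),
                 character(1))
  list(seq = seq, qual = qual, nsub = rowSums(err))
}

#' Simulate error-bearing paired-end reads from a sample mixture
#'
#' Templates are drawn multinomially from `mixture`; with probability
#' `chimera_rate` a read instead derives from a two-parent crossover at a
#' uniform breakpoint. The forward mate covers the first `read_len` bases of
#' the template and the reverse mate the reverse complement of the last
#' `read_len` bases. Per-base substitutions are injected according to the
#' error model's quality-dependent probability. Origin tags are retained for
#' ground-truth evaluation.
#'
#' @param mixture named fraction vector from [compose_sample()].
#' @param refs a `reference_set`.
#' @param contam a `contaminant_pool` or NULL.
#' @param model an `error_model`.
#' @param depth number of read pairs (>= 1).
#' @param seed integer seed.
#' @param sample_name prefix for read ids.
#' @return a data.frame of class `read_pairs` with columns `read_id`,
#'   `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`, `origin_id`,
#'   `origin_class`, `n_substitutions`.
#' @export
sequence_reads <- function(mixture, refs, contam, model, depth, seed = 1L,
                           sample_name = "sample") {
  stopifnot(inherits(model, "error_model"), depth >= 1)
  set.seed(seed)
  al <- reference_alleles(refs)
  templates <- setNames(al$sequence, al$template_id)
  if (!is.null(contam)) {
    templates <- c(templates, setNames(contam$sequence, contam$contam_id))
  }
  templates <- templates[names(mixture)]
  if (anyNA(templates)) stop("mixture names must match template ids")
  tlen <- unique(nchar(templates))
  if (length(tlen) != 1) stop("all templates must share one amplicon length")
  if (model$read_len > tlen) {
    stop("read length exceeds amplicon length")
  }
  cls <- attr(mixture, "origin_class")

  origin <- sample(names(mixture), depth, replace = TRUE, prob = mixture)
  origin_class <- unname(cls[origin])
  is_chim <- runif(depth) < model$chimera_rate
  tpl_seq <- unname(templates[origin])
  if (any(is_chim)) {
    idx <- which(is_chim)
    for (i in idx) {
      pair <- sample(names(mixture), 2, replace = FALSE, prob = mixture)
      b <- sample(seq_len(tlen - 1), 1)
      tpl_seq[i] <- paste0(substr(templates[pair[1]], 1, b),
                           substr(templates[pair[2]], b + 1, tlen))
      origin[i] <- paste0("chimera:", pair[1], "|", pair[2], "@", b)
      origin_class[i] <- "chimera"
    }
  }

  L <- model$read_len
  qf <- seq(model$mean_q_fwd[1], model$mean_q_fwd[2], length.out = L)
  qr <- seq(model$mean_q_rev[1], model$mean_q_rev[2], length.out = L)
  fwd_seq <- fwd_qual <- rev_seq <- rev_qual <- character(depth)
  nsub <- integer(depth)
  for (tpl in unique(tpl_seq)) {
    idx <- which(tpl_seq == tpl)
    tint <- match(strsplit(tpl, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
    f <- .simulate_mate(tint[seq_len(L)], length(idx), qf, model$sd_q,
                        model$substitution_prob)
    rint <- rev(3L - tint)[seq_len(L)] # reverse complement, 3' end first
    r <- .simulate_mate(rint, length(idx), qr, model$sd_q,
                        model$substitution_prob)
    fwd_seq[idx] <- f$seq; fwd_qual[idx] <- f$qual
    rev_seq[idx] <- r$seq; rev_qual[idx] <- r$qual
    nsub[idx] <- f$nsub + r$nsub
  }
  out <- data.frame(
    read_id = sprintf("%s_read%06d", sample_name, seq_len(depth)),
    fwd_seq = fwd_seq, fwd_qual = fwd_qual,
    rev_seq = rev_seq, rev_qual = rev_qual,
    origin_id = origin, origin_class = origin_class,
    n_substitutions = nsub,
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Simulate a full dilution series
#'
#' Composes and sequences every sample of a dilution design. Per-sample
#' seeds are derived deterministically from `seed`.
#'
#' @inheritParams sequence_reads
#' @param design a `dilution_design`.
#' @param outdir optional directory; if given, paired FASTQ files
#'   (`sample_k_R1.fastq`, `sample_k_R2.fastq`), community FASTA files and a
#'   ground-truth origin table (TSV) are written there.
#' @param gzip write gzipped FASTQ.
#' @return named list of `read_pairs`, one per sample (`sample_1`, ...).
#' @export
simulate_dilution_series <- function(refs, contam, design, model, seed = 1L,
                                     outdir = NULL, gzip = FALSE) {
  samples <- vector("list", design$n_samples)
  names(samples) <- paste0("sample_", seq_len(design$n_samples))
  for (k in seq_len(design$n_samples)) {
    mix <- compose_sample(refs, contam, design, k)
    samples[[k]] <- sequence_reads(mix, refs, contam, model,
                                   design$depth_per_sample[k],
                                   seed = derive_seed(seed, k),
                                   sample_name = names(samples)[k])
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_community_fasta(refs, file.path(outdir, "references.fasta"))
    if (!is.null(contam)) {
      write_community_fasta(contam, file.path(outdir, "contaminants.fasta"))
    }
    origin <- do.call(rbind, lapply(samples, function(s) {
      s[, c("read_id", "origin_id", "origin_class")]
    }))
    write.table(origin, file.path(outdir, "origins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (k in seq_len(design$n_samples)) {
      write_sample_fastq(samples[[k]], outdir, names(samples)[k], gzip = gzip)
    }
  }
  samples
}

#' Write one sample's read pairs as paired FASTQ
#'
#' @param pairs a `read_pairs` data.frame.
#' @param dir output directory.
#' @param sample_name file prefix.
#' @param gzip compress output.
#' @return character vector of the two paths, invisibly.
#' @export
write_sample_fastq <- function(pairs, dir, sample_name, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(sample_name, "_R1", ext))
  p2 <- file.path(dir, paste0(sample_name, "_R2", ext))
  f <- Biostrings::DNAStringSet(setNames(pairs$fwd_seq, pairs$read_id))
  r <- Biostrings::DNAStringSet(setNames(pairs$rev_seq, pairs$read_id))
  Biostrings::writeXStringSet(f, p1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$fwd_qual),
                              compress = gzip)
  Biostrings::writeXStringSet(r, p2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$rev_qual),
                              compress = gzip)
  invisible(c(p1, p2))
}

#' Read paired FASTQ files into a `read_pairs` table
#'
#' @param fq1,fq2 forward and reverse FASTQ paths (gzip-aware).
#' @return a `read_pairs` data.frame (origin columns NA).
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  f <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  if (length(f) != length(r)) stop("mates differ in read count")
  out <- data.frame(
    read_id = names(f),
    fwd_seq = as.character(f),
    fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
    rev_seq = as.character(r),
    rev_qual = as.character(S4Vectors::mcols(r)$qualities),
    origin_id = NA_character_, origin_class = NA_character_,
    n_substitutions = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}
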