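# shared fixture builders; everything is generated in code

# substitute bases of `seq` at `pos` (deterministic: next base in ACGT order)
sub_at <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- bases[(match(chars[p], bases)) %% 4 + 1]
  }
  paste(chars, collapse = "")
}

# a read_pairs row built from explicit mate sequences and Phred integers
make_pair <- function(fwd, rev, q_fwd = 30L, q_rev = 30L, id = "r1",
                      origin = "t1", origin_class = "reference") {
  qf <- paste(rawToChar(as.raw(rep_len(q_fwd, nchar(fwd)) + 33L)),
              collapse = "")
  qr <- paste(rawToChar(as.raw(rep_len(q_rev, nchar(rev)) + 33L)),
              collapse = "")
  out <- data.frame(read_id = id, fwd_seq = fwd, fwd_qual = qf,
                    rev_seq = rev, rev_qual = qr, origin_id = origin,
                    origin_class = origin_class, n_substitutions = 0L,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

# paired reads covering a full template: fwd = 5' read_len bases,
# rev = reverse complement of the 3' read_len bases
pair_from_template <- function(template, read_len = nchar(template),
                               q = 30L, id = "r1") {
  L <- nchar(template)
  fwd <- substr(template, 1, read_len)
  rev <- revcomp(substr(template, L - read_len + 1, L))
  make_pair(fwd, rev, q, q, id = id)
}

# a merged_reads table with one row per read (repeating unique sequences)
fake_merged <- function(seqs, counts, q = 30L) {
  sequence <- rep(seqs, counts)
  out <- data.frame(
    read_id = if (length(sequence)) sprintf("r%06d", seq_along(sequence))
              else character(0),
    sequence = sequence,
    quality = strrep(rawToChar(as.raw(q + 33L)), nchar(sequence)),
    origin_id = rep(NA_character_, length(sequence)),
    origin_class = rep(NA_character_, length(sequence)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("merged_reads", "data.frame")
  out
}

# a derep built directly from unique sequences and per-sample counts
fake_derep <- function(seqs, counts) {
  if (is.null(dim(counts))) {
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(NULL, "sample_1"))
  }
  ab <- rowSums(counts)
  ord <- order(-ab, seqs)
  structure(list(sequence = seqs[ord], abundance = as.integer(ab[ord]),
                 counts = counts[ord, , drop = FALSE]),
            class = "derep")
}

# error model with no substitutions and no chimeras
perfect_model <- function(read_len = 251L) {
  error_model(read_len = read_len, sd_q = 0,
              substitution_prob = function(q) rep(0, length(q)),
              chimera_rate = 0)
}

# independent greedy-OTU oracle: plain transcription of the clustering rule
# using utils::adist only
oracle_greedy_otu <- function(seqs, abundance, radius) {
  ord <- order(-abundance, seqs)
  seqs <- seqs[ord]; abundance <- abundance[ord]
  seeds <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- NA_integer_
    for (s in seq_along(seeds)) {
      d <- utils::adist(seqs[i], seqs[seeds[s]])[1, 1]
      alen <- max(nchar(seqs[i]), nchar(seqs[seeds[s]]))
      if (d <= radius * alen) { hit <- s; break }
    }
    if (is.na(hit)) {
      seeds <- c(seeds, i)
      assign[i] <- length(seeds)
    } else {
      assign[i] <- hit
    }
  }
  list(features = seqs[seeds],
       totals = vapply(seq_along(seeds),
                       function(s) sum(abundance[assign == s]), numeric(1)))
}
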