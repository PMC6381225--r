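#' @useDynLib ampbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm setNames median quantile ppois cor uniroot
#' @importFrom utils write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (52.5 -> 53), the convention used throughout the package's percentage
#' summaries. Base R's `round()` uses round-half-to-even, which disagrees on
#' exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len sequence length (single integer, recycled).
#' @return character vector of A/C/G/T strings.
#' @export
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

## substitute k random positions with a different base
mutate_substitutions <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## phred integer vector <-> phred+33 string
phred_to_string <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

## seed fan-out: derive a per-stage seed from the run seed; keeps results
## below 2^31 and distinct across stages
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stage) * 97) %%
               2147483647)
}
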