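#' Construct a reference community
#'
#' A `reference_set` holds the ground-truth community: named strains, one or
#' more 16S amplicon alleles per strain, and the genomic proportion of each
#' strain in the mock mixture.
#'
#' @param strain_id character vector of strain names.
#' @param alleles list of character vectors, one per strain; each vector
#'   holds that strain's distinct allele sequences.
#' @param genomic_proportion numeric vector of strain proportions; must sum
#'   to 1 (tolerance 1e-9). Defaults to uniform.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(strain_id, alleles, genomic_proportion = NULL) {
  stopifnot(length(strain_id) == length(alleles), length(strain_id) >= 1)
  if (is.null(genomic_proportion)) {
    genomic_proportion <- rep(1 / length(strain_id), length(strain_id))
  }
  stopifnot(length(genomic_proportion) == length(strain_id))
  if (abs(sum(genomic_proportion) - 1) > 1e-9) {
    stop("genomic proportions must sum to 1")
  }
  for (a in alleles) {
    if (length(a) < 1) stop("every strain needs at least one allele")
    if (anyDuplicated(a)) stop("alleles within a strain must be distinct")
  }
  all_alleles <- unlist(alleles, use.names = FALSE)
  if (anyDuplicated(all_alleles)) stop("alleles must be distinct across strains")
  structure(
    list(strain_id = as.character(strain_id),
         alleles = alleles,
         genomic_proportion = genomic_proportion),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$strain_id), "strains,",
      sum(lengths(x$alleles)), "alleles\n")
  invisible(x)
}

#' Flatten a reference set to one row per allele
#'
#' @param refs a `reference_set`.
#' @return data.frame with columns `template_id`, `strain_id`, `sequence`.
#' @export
reference_alleles <- function(refs) {
  stopifnot(inherits(refs, "reference_set"))
  n <- lengths(refs$alleles)
  data.frame(
    template_id = unlist(lapply(seq_along(refs$strain_id), function(i) {
      paste0(refs$strain_id[i], "_allele", seq_len(n[i]))
    })),
    strain_id = rep(refs$strain_id, n),
    sequence = unlist(refs$alleles, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic reference community
#'
#' Draws random amplicon sequences for `n_strains` strains such that all
#' inter-strain allele pairs are at least `min_pairwise_dist` edits apart.
#' Within a strain, additional alleles differ from the first by 1 to 3
#' substitutions (real 16S operons typically differ by a few bases).
#' Deterministic for a fixed seed; fails explicitly if the distance
#' constraint cannot be met within a bounded number of redraws.
#'
#' @param n_strains number of strains (>= 1).
#' @param amplicon_len amplicon length in bases.
#' @param min_pairwise_dist minimum Levenshtein distance between alleles of
#'   different strains.
#' @param allele_spec integer vector of allele counts per strain (recycled);
#'   default 1.
#' @param genomic_proportion strain proportions; default uniform.
#' @param seed integer seed.
#' @param max_retries redraw budget per strain before failing.
#' @return a `reference_set`.
#' @export
generate_reference_set <- function(n_strains, amplicon_len, min_pairwise_dist,
                                   allele_spec = 1L, genomic_proportion = NULL,
                                   seed = 1L, max_retries = 100L) {
  stopifnot(n_strains >= 1, min_pairwise_dist >= 1,
            amplicon_len >= min_pairwise_dist)
  allele_spec <- rep_len(as.integer(allele_spec), n_strains)
  set.seed(seed)
  base_seqs <- character(0)
  for (i in seq_len(n_strains)) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      cand <- random_dna(1, amplicon_len)
      if (length(base_seqs) == 0 ||
          all(seq_dist_matrix(cand, base_seqs, min_pairwise_dist) >=
              min_pairwise_dist)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place strain ", i, " at distance >= ",
           min_pairwise_dist, " after ", max_retries, " retries")
    }
    base_seqs <- c(base_seqs, cand)
  }
  alleles <- lapply(seq_len(n_strains), function(i) {
    out <- base_seqs[i]
    while (length(out) < allele_spec[i]) {
      cand <- mutate_substitutions(base_seqs[i], sample(1:3, 1))
      if (!cand %in% out) out <- c(out, cand)
    }
    out
  })
  reference_set(sprintf("strain%02d", seq_len(n_strains)), alleles,
                genomic_proportion)
}

#' Construct a contaminant pool
#'
#' A fixed-mass pool of contaminant template sequences standing in for
#' reagent and laboratory contamination. Relative masses must sum to 1;
#' sequences must be distinct from every reference allele.
#'
#' @param contam_id character vector of contaminant names.
#' @param sequence character vector of contaminant amplicon sequences.
#' @param relative_mass numeric vector summing to 1.
#' @param total_mass total pool mass in the same arbitrary units as the
#'   dilution design's template mass.
#' @param refs optional `reference_set` checked for sequence collisions.
#' @return an object of class `contaminant_pool`.
#' @export
contaminant_pool <- function(contam_id, sequence, relative_mass = NULL,
                             total_mass = 1, refs = NULL) {
  stopifnot(length(contam_id) == length(sequence), total_mass >= 0)
  if (is.null(relative_mass)) {
    relative_mass <- rep(1 / length(sequence), length(sequence))
  }
  if (abs(sum(relative_mass) - 1) > 1e-9) {
    stop("relative masses must sum to 1")
  }
  if (anyDuplicated(sequence)) stop("contaminant sequences must be distinct")
  if (!is.null(refs)) {
    if (any(sequence %in% reference_alleles(refs)$sequence)) {
      stop("contaminant sequences must differ from all reference alleles")
    }
  }
  structure(
    list(contam_id = as.character(contam_id), sequence = sequence,
         relative_mass = relative_mass, total_mass = total_mass),
    class = "contaminant_pool"
  )
}

#' @export
print.contaminant_pool <- function(x, ...) {
  cat("contaminant_pool:", length(x$contam_id), "templates, total mass",
      x$total_mass, "\n")
  invisible(x)
}

#' Generate a synthetic contaminant pool
#'
#' Random sequences at least `min_dist` edits from every reference allele
#' (and from each other), so that Reference and Contaminant categories are
#' unambiguous by construction. Relative masses default to normalized
#' log-normal draws: reagent contaminants are typically few dominant taxa
#' plus a long tail, not a uniform pool.
#'
#' @param n number of contaminant templates.
#' @param amplicon_len sequence length (use the reference amplicon length so
#'   that merged read lengths stay in one window).
#' @param refs `reference_set` to keep distance from.
#' @param min_dist minimum Levenshtein distance to references and between
#'   contaminants.
#' @param total_mass pool mass (constant across dilution samples).
#' @param mass_sdlog sdlog of the log-normal relative-mass draw; 0 gives a
#'   uniform pool.
#' @param seed integer seed.
#' @param max_retries redraw budget per template.
#' @return a `contaminant_pool`.
#' @export
generate_contaminant_pool <- function(n, amplicon_len, refs, min_dist = 20L,
                                      total_mass = 0.001, mass_sdlog = 1,
                                      seed = 2L, max_retries = 100L) {
  stopifnot(n >= 1)
  set.seed(seed)
  avoid <- reference_alleles(refs)$sequence
  seqs <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      cand <- random_dna(1, amplicon_len)
      if (all(seq_dist_matrix(cand, c(avoid, seqs), min_dist) >= min_dist)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place contaminant ", i, " at distance >= ", min_dist)
    seqs <- c(seqs, cand)
  }
  mass <- if (mass_sdlog > 0) rlnorm(n, 0, mass_sdlog) else rep(1, n)
  contaminant_pool(sprintf("contam%03d", seq_len(n)), seqs,
                   mass / sum(mass), total_mass, refs = refs)
}

#' Restrict a community to the merged-read window
#'
#' Preprocessing trims `head_trim` cycles from the 5' end of both mates, so
#' a merged read covers template positions `head_trim + 1` through
#' `amplicon_len - head_trim`. To compare inferred features against the
#' known community by exact match, the reference (and contaminant)
#' sequences must be windowed the same way.
#'
#' @param x a `reference_set` or `contaminant_pool`.
#' @param start,end 1-based window bounds on the template.
#' @return an object of the same class with windowed sequences.
#' @export
window_community <- function(x, start, end) {
  stopifnot(start >= 1, end >= start)
  if (inherits(x, "reference_set")) {
    reference_set(x$strain_id,
                  lapply(x$alleles, substr, start = start, stop = end),
                  x$genomic_proportion)
  } else if (inherits(x, "contaminant_pool")) {
    contaminant_pool(x$contam_id, substr(x$sequence, start, end),
                     x$relative_mass, x$total_mass)
  } else {
    stop("unsupported object")
  }
}

#' Write reference or contaminant sequences as FASTA
#'
#' @param x a `reference_set` or `contaminant_pool`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(x, path) {
  if (inherits(x, "reference_set")) {
    al <- reference_alleles(x)
    ss <- Biostrings::DNAStringSet(setNames(al$sequence, al$template_id))
  } else if (inherits(x, "contaminant_pool")) {
    ss <- Biostrings::DNAStringSet(setNames(x$sequence, x$contam_id))
  } else {
    stop("unsupported object")
  }
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
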