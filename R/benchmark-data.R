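#' Published high-biomass benchmark summaries
#'
#' Bundled summary tables from a published benchmark of the six inference
#' strategies on four undiluted mock communities (Zymo, 8 strains; Kozich,
#' 21; Schirmer, 57; D'Amore, 53): per-category feature counts and the
#' recall / precision percentages reported alongside them. Used as a
#' fixture for round-trip consistency checks of the package's precision
#' formulas; the raw sequence data behind these summaries is not shipped.
#'
#' One known quirk: for the `dada` x `Schirmer` cell the printed technical
#' precision (96) differs by one point from the value its own category
#' counts imply (57/59 = 96.6 -> 97 under half-up rounding); the
#' `deviating` attribute of the precision table marks that row.
#'
#' @return list with `category_counts` and `precision` data.frames.
#' @export
highbiomass_benchmark <- function() {
  cc <- read.delim(system.file("extdata", "highbiomass_category_counts.tsv",
                               package = "ampbench"),
                   stringsAsFactors = FALSE)
  pr <- read.delim(system.file("extdata", "highbiomass_precision.tsv",
                               package = "ampbench"),
                   stringsAsFactors = FALSE)
  attr(pr, "deviating") <- pr$dataset == "Schirmer" & pr$method == "dada"
  list(category_counts = cc, precision = pr)
}

#' Recompute precision percentages from category counts
#'
#' Applies [overall_precision()] and [technical_precision()] to each row of
#' a category-count table shaped like
#' `highbiomass_benchmark()$category_counts`.
#'
#' @param cc category-count data.frame.
#' @return data.frame `dataset`, `method`, `overall_precision`,
#'   `technical_precision`.
#' @export
recompute_precision <- function(cc) {
  out <- data.frame(
    dataset = cc$dataset, method = cc$method,
    overall_precision = vapply(seq_len(nrow(cc)), function(i) {
      overall_precision(c(total = cc$total[i], Reference = cc$reference[i]))
    }, numeric(1)),
    technical_precision = vapply(seq_len(nrow(cc)), function(i) {
      technical_precision(c(Reference = cc$reference[i],
                            RefNoisy = cc$ref_noisy[i]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out
}
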