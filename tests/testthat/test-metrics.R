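test_that("recall percentages reproduce the printed ratios", {
  expect_equal(recall_pct(46, 57), 81)
  expect_equal(recall_pct(20, 21), 95)
  expect_equal(recall_pct(42, 53), 79)
  expect_equal(recall_pct(0, 10), 0)
  # allele hits above the strain count cap at 100
  expect_equal(recall_pct(9, 8), 100)
})

test_that("precision formulas reproduce their worked examples", {
  expect_equal(overall_precision(c(total = 12, Reference = 9)), 75)
  expect_equal(overall_precision(c(total = 200, Reference = 8)), 4)
  expect_equal(overall_precision(c(total = 5, Reference = 5)), 100)
  expect_equal(technical_precision(c(Reference = 9, RefNoisy = 2)), 82)
  expect_equal(technical_precision(c(Reference = 8, RefNoisy = 1)), 89)
  expect_equal(technical_precision(c(Reference = 7, RefNoisy = 0)), 100)
  # ties round away from zero, not to even
  expect_equal(overall_precision(c(total = 40, Reference = 21)), 53)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
})

test_that("bundled benchmark precision cells round-trip from their counts", {
  bm <- highbiomass_benchmark()
  rec <- recompute_precision(bm$category_counts)
  dev <- attr(bm$precision, "deviating")
  expect_equal(sum(dev), 1)
  # all regular cells reproduce the printed percentages exactly
  expect_equal(rec$overall_precision, bm$precision$overall_precision)
  expect_equal(rec$technical_precision[!dev],
               bm$precision$technical_precision[!dev])
  # the single deviating cell computes to 97 (57 / 59 rounded half up),
  # one point above the printed value
  expect_equal(rec$technical_precision[dev], 97)
  expect_equal(bm$precision$technical_precision[dev], 96)
})

test_that("read fractions and category fractions are consistent", {
  set.seed(101)
  R1 <- random_dna(1, 80)
  refs <- reference_set("s1", list(R1))
  other <- random_dna(1, 80)
  tab <- feature_table(c(R1, other), matrix(c(956L, 44L), ncol = 1))
  cl <- classify_features(tab, refs, NULL)
  expect_equal(reference_read_fraction(cl), 95.6)
  fr <- category_read_fractions(cl)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(unname(fr[["Reference"]] * 100), 95.6)
  # all reads in Reference features
  tab2 <- feature_table(R1, matrix(1000L, ncol = 1))
  expect_equal(reference_read_fraction(classify_features(tab2, refs, NULL)),
               100.0)
  # no Reference features at all
  tab3 <- feature_table(other, matrix(1000L, ncol = 1))
  expect_equal(reference_read_fraction(classify_features(tab3, refs, NULL)),
               0.0)
})

test_that("diversity indices hit closed forms and bounds", {
  expect_equal(shannon_index(rep(5, 8)), log(8))
  expect_equal(inv_simpson(rep(5, 8)), 8)
  expect_equal(shannon_index(1), 0)
  expect_equal(inv_simpson(1), 1)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_equal(inv_simpson(c(0.5, 0.5)), 2)
  # Shannon <= ln S with equality iff uniform; inverse Simpson <= S
  set.seed(102)
  for (i in 1:20) {
    x <- rlnorm(sample(2:30, 1))
    expect_lte(shannon_index(x), log(length(x)) + 1e-12)
    expect_lte(inv_simpson(x), length(x) + 1e-12)
  }
  expect_lt(shannon_index(rlnorm(10, 0, 1.5)), log(10))
})

test_that("Fisher's alpha solves its defining equation", {
  a <- fisher_alpha(8, 100000)
  expect_equal(a * log1p(100000 / a), 8, tolerance = 1e-8)
  expect_equal(a, 0.672, tolerance = 1e-3)
  # independent bisection oracle on random (S, N) pairs
  set.seed(103)
  for (i in 1:100) {
    N <- sample(1000:200000, 1)
    S <- sample(2:min(500, N - 1), 1)
    got <- fisher_alpha(S, N)
    lo <- 1e-10; hi <- 1e6
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (mid * log1p(N / mid) < S) lo <- mid else hi <- mid
    }
    expect_equal(got, (lo + hi) / 2, tolerance = 1e-6)
  }
  # doubling N at fixed S strictly decreases alpha
  expect_lt(fisher_alpha(20, 200000), fisher_alpha(20, 100000))
  # undefined cases fail explicitly
  expect_error(fisher_alpha(0, 100))
  expect_error(fisher_alpha(100, 100))
})

test_that("Fisher's alpha matches the community-ecology reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(104)
  for (i in 1:20) {
    N <- sample(500:50000, 1)
    S <- sample(2:100, 1)
    x <- c(rep(1, S - 1), N - S + 1)   # S species, N individuals
    expect_equal(fisher_alpha(S, N),
                 unname(vegan::fisher.alpha(x)), tolerance = 1e-4)
  }
})

test_that("depth normalization follows both conventions", {
  expect_equal(normalized_feature_total(100, 5000, 5000), 100)
  expect_equal(normalized_feature_total(100, 10000, 5000), 200)
  expect_equal(normalized_feature_total(100, 10000, 5000, invert = TRUE), 50)
})

test_that("signal and noise summaries report medians and overlap", {
  set.seed(105)
  R1 <- random_dna(1, 80)
  refs <- reference_set("s1", list(R1))
  others <- vapply(1:3, function(i) random_dna(1, 80), character(1))
  tab <- feature_table(c(R1, others),
                       matrix(c(10000L, 100L, 50L, 20L), ncol = 1))
  cl <- classify_features(tab, refs, NULL)
  sn <- signal_noise_summary(cl)
  expect_equal(sn$signal$median, log10(10000))
  expect_equal(sn$noise$median, log10(50))
  expect_equal(sn$overlap,
               log10(10000) - unname(quantile(log10(c(100, 50, 20)), 0.75)))
  # noise absent: flagged, not fabricated
  tab2 <- feature_table(R1, matrix(100L, ncol = 1))
  sn2 <- signal_noise_summary(classify_features(tab2, refs, NULL))
  expect_equal(sn2$noise$n, 0)
  expect_true(is.na(sn2$overlap))
})

test_that("expected alpha diversity comes from design proportions", {
  ea <- expected_alpha(rep(1 / 8, 8), n_reads = 100000)
  expect_equal(ea[["shannon"]], log(8))
  expect_equal(ea[["inv_simpson"]], 8)
  expect_equal(ea[["fisher"]], fisher_alpha(8, 100000))
  # skewed proportions sit below the maximum-entropy bound
  set.seed(106)
  p <- rlnorm(12); p <- p / sum(p)
  expect_lt(expected_alpha(p)[["shannon"]], log(12))
  # single strain: zero entropy, unit Simpson, Fisher undefined -> NA
  e1 <- expected_alpha(1, n_reads = 100)
  expect_equal(e1[["shannon"]], 0)
  expect_equal(e1[["inv_simpson"]], 1)
  expect_true(is.na(e1[["fisher"]]))
})
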