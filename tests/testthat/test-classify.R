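make_classify_fixture <- function() {
  set.seed(91)
  R1 <- random_dna(1, 100)
  C1 <- random_dna(1, 100)            # far from R1 (random pair)
  refs <- reference_set("s1", list(R1))
  ctm <- contaminant_pool("c1", C1)
  rn <- sub_at(R1, c(4, 44, 84))      # 3 nt from R1
  cn <- sub_at(C1, c(12, 70))         # 2 nt from C1
  other <- random_dna(1, 100)
  tab <- feature_table(c(R1, rn, C1, cn, other),
                       matrix(c(1000L, 50L, 400L, 30L, 10L), ncol = 1))
  list(refs = refs, ctm = ctm, tab = tab,
       seqs = list(R1 = R1, rn = rn, C1 = C1, cn = cn, other = other))
}

test_that("the five-category precedence classifies a constructed fixture", {
  fx <- make_classify_fixture()
  # verify the construction with an exhaustive distance computation
  d <- utils::adist(fx$tab$sequence)
  cl <- classify_features(fx$tab, fx$refs, fx$ctm)
  got <- setNames(as.character(cl$category), cl$sequence)
  expect_equal(unname(got[fx$seqs$R1]), "Reference")
  expect_equal(unname(got[fx$seqs$rn]), "RefNoisy")
  expect_equal(unname(got[fx$seqs$C1]), "Contaminant")
  expect_equal(unname(got[fx$seqs$cn]), "ContamNoisy")
  expect_equal(unname(got[fx$seqs$other]), "Other")
  expect_equal(cl$distance[cl$sequence == fx$seqs$R1], 0L)
  expect_equal(cl$distance[cl$sequence == fx$seqs$rn],
               utils::adist(fx$seqs$rn, fx$seqs$R1)[1, 1])
  # categories partition the table
  expect_equal(sum(category_counts(cl)[-1]), nrow(cl))
})

test_that("category counts partition and handle edge tables", {
  fx <- make_classify_fixture()
  cl <- classify_features(fx$tab, fx$refs, fx$ctm)
  cc <- category_counts(cl)
  expect_equal(cc[["total"]], 5)
  expect_equal(unname(cc[c("Reference", "RefNoisy", "Contaminant",
                           "ContamNoisy", "Other")]),
               c(1L, 1L, 1L, 1L, 1L))
  # all-Reference table
  refs2 <- reference_set(c("a", "b"),
                         list(fx$seqs$R1, fx$seqs$other))
  tab2 <- feature_table(c(fx$seqs$R1, fx$seqs$other),
                        matrix(c(10L, 5L), ncol = 1))
  cc2 <- category_counts(classify_features(tab2, refs2, NULL))
  expect_equal(unname(cc2[c("total", "Reference")]), c(2L, 2L))
  expect_equal(sum(cc2[c("RefNoisy", "Contaminant", "ContamNoisy",
                         "Other")]), 0)
  # empty reference set fails
  expect_error(classify_features(fx$tab, NULL, fx$ctm), "empty reference")
})

test_that("noisy assignments require the configured abundance ordering", {
  fx <- make_classify_fixture()
  # satellite more abundant than its Reference anchor: not RefNoisy
  tab <- feature_table(c(fx$seqs$R1, fx$seqs$rn),
                       matrix(c(100L, 200L), ncol = 1))
  cl <- classify_features(tab, fx$refs, fx$ctm)
  expect_equal(as.character(cl$category[cl$sequence == fx$seqs$rn]),
               "Other")
  # with the flag off it becomes RefNoisy
  cl2 <- classify_features(tab, fx$refs, fx$ctm,
                           classify_params(require_lower_abundance_for_noisy = FALSE))
  expect_equal(as.character(cl2$category[cl2$sequence == fx$seqs$rn]),
               "RefNoisy")
  # ContamNoisy needs no abundance ordering: satellite above its anchor
  tab3 <- feature_table(c(fx$seqs$C1, fx$seqs$cn),
                        matrix(c(100L, 400L), ncol = 1))
  cl3 <- classify_features(tab3, fx$refs, fx$ctm)
  expect_equal(as.character(cl3$category[cl3$sequence == fx$seqs$cn]),
               "ContamNoisy")
})

test_that("widening the noisy radius never shrinks the satellite classes", {
  set.seed(92)
  R1 <- random_dna(1, 80)
  refs <- reference_set("s1", list(R1))
  seqs <- c(R1, vapply(c(1, 3, 6, 9, 12, 15),
                       function(k) sub_at(R1, sample(80, k)), character(1)))
  tab <- feature_table(seqs, matrix(c(1000L, rep(10L, 6)), ncol = 1))
  prev <- -1
  for (k in c(0, 2, 5, 10, 16)) {
    cc <- category_counts(classify_features(tab, refs, NULL,
                                            classify_params(max_noisy_dist = k)))
    noisy <- cc[["RefNoisy"]] + cc[["ContamNoisy"]]
    expect_gte(noisy, prev)
    prev <- noisy
  }
})

test_that("classification is independent of input ordering", {
  fx <- make_classify_fixture()
  perm <- c(3, 5, 1, 2, 4)
  tab_p <- feature_table(fx$tab$sequence[perm],
                         fx$tab$counts[perm, , drop = FALSE])
  cl_a <- classify_features(fx$tab, fx$refs, fx$ctm)
  cl_b <- classify_features(tab_p, fx$refs, fx$ctm)
  expect_identical(cl_a$sequence, cl_b$sequence)
  expect_identical(cl_a$category, cl_b$category)
})

test_that("classification agrees with ground-truth origins on simulation", {
  refs <- generate_reference_set(5, 253, 20, seed = 93)
  ctm <- generate_contaminant_pool(8, 253, refs, min_dist = 20, seed = 94)
  des <- dilution_design(n_samples = 9, contaminant_mass = 0.01,
                         depth_per_sample = 3000)
  mix <- compose_sample(refs, ctm, des, 6)   # contamination well represented
  em <- error_model(chimera_rate = 0)
  rp <- sequence_reads(mix, refs, ctm, em, 3000, seed = 95)
  pp <- preprocess_sample(rp)
  tab <- infer_features(pp, "unoise")
  mapped <- map_reads_to_features(pp, tab)
  rw <- window_community(refs, 16, 238)
  cw <- window_community(ctm, 16, 238)
  cl <- classify_features(mapped, rw, cw)
  ref_seqs <- reference_alleles(rw)$sequence
  # every Reference-classified feature is a true community sequence and
  # every Contaminant-classified feature a true contaminant
  expect_true(all(cl$sequence[cl$category == "Reference"] %in% ref_seqs))
  expect_true(all(cl$sequence[cl$category == "Contaminant"] %in% cw$sequence))
  # and the true templates that were sequenced deeply are all recovered
  expect_true(all(ref_seqs %in% cl$sequence[cl$category == "Reference"]))
})
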