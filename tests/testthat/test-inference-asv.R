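# UNOISE-, Deblur- and DADA-style denoisers

test_that("the abundance-skew curve evaluates and decreases as printed", {
  expect_equal(unoise_beta(0, 2), 0.5)
  expect_equal(unoise_beta(1, 2), 0.125)
  expect_equal(unoise_beta(2, 2), 0.03125)
  expect_equal(unoise_beta(0:10, 2), 1 / 2^(2 * (0:10) + 1))
  expect_true(all(diff(unoise_beta(0:20, 1.5)) < 0))
})

test_that("skew denoising merges or splits on the beta boundary", {
  set.seed(71)
  M <- random_dna(1, 100)
  v <- sub_at(M, 42)  # distance 1
  # skew 0.1 <= beta(1) = 0.125: merged
  t1 <- denoise_unoise(fake_derep(c(M, v), c(1000, 100)))
  expect_equal(t1$sequence, M)
  expect_equal(t1$abundance, 1100)
  # skew 0.2 > 0.125: two features
  t2 <- denoise_unoise(fake_derep(c(M, v), c(1000, 200)))
  expect_setequal(t2$sequence, c(M, v))
  # identical sequences only -> one feature
  t3 <- denoise_unoise(dereplicate(fake_merged(M, 7)))
  expect_equal(t3$sequence, M)
})

test_that("skew denoising approaches its alpha limits", {
  set.seed(72)
  M <- random_dna(1, 100)
  seqs <- c(M, sub_at(M, 10), sub_at(M, c(20, 30)), sub_at(M, c(1, 50, 99)))
  ab <- c(100, 40, 10, 4)   # every skew <= 0.5
  # alpha large: beta(d >= 1) ~ 0, one feature per unique sequence
  expect_equal(n_features(denoise_unoise(fake_derep(seqs, ab),
                                         unoise_params(alpha = 100))), 4)
  # alpha tiny: beta(d) ~ 1/2 for all d, everything joins the top centroid
  tiny <- denoise_unoise(fake_derep(seqs, ab), unoise_params(alpha = 1e-9))
  expect_equal(tiny$sequence, M)
  expect_equal(tiny$abundance, sum(ab))
})

test_that("error subtraction removes or shrinks neighbors as configured", {
  set.seed(73)
  M <- random_dna(1, 100)
  v <- sub_at(M, 55)
  prof <- c(0.06, rep(0, 10))
  # 1000 * 0.06 = 60 >= 30: variant removed
  t1 <- denoise_deblur(fake_derep(c(M, v), c(1000, 30)),
                       deblur_params(error_profile = prof))
  expect_equal(t1$sequence, M)
  # variant at 100 survives with residual 40
  t2 <- denoise_deblur(fake_derep(c(M, v), c(1000, 100)),
                       deblur_params(error_profile = prof))
  expect_setequal(t2$sequence, c(M, v))
  expect_equal(unname(attr(t2, "residual")[v]), 40)
  expect_equal(t2$abundance[t2$sequence == v], 40)

  # zero profile: identity on unique sequences
  d <- fake_derep(c(M, v, sub_at(M, c(2, 3))), c(500, 20, 5))
  t0 <- denoise_deblur(d, deblur_params(error_profile = rep(0, 11)))
  expect_setequal(t0$sequence, d$sequence)
  expect_equal(sort(t0$abundance), sort(as.numeric(d$abundance)))

  # no counts are ever created
  expect_lte(sum(t2$abundance), 1100)

  # positional model refuses mixed lengths
  expect_error(denoise_deblur(fake_derep(c("ACGT", "ACGTA"), c(5, 4))),
               "equal-length")
})

test_that("iterative error-model denoising separates true templates only", {
  set.seed(74)
  A <- random_dna(1, 120)
  B <- sub_at(A, c(10, 30, 50, 70, 90))  # distance 5
  # two strong templates split (Poisson tail far below omega)
  t1 <- denoise_dada(fake_derep(c(A, B), c(1000, 1000)))
  expect_setequal(t1$sequence, c(A, B))
  # a low-abundance 1-off variant stays merged with its template
  v <- sub_at(A, 60)
  t2 <- denoise_dada(fake_derep(c(A, v), c(1000, 5)))
  expect_equal(t2$sequence, A)
  expect_equal(t2$abundance, 1005)
  # all reads identical -> one feature
  t3 <- denoise_dada(dereplicate(fake_merged(A, 50)))
  expect_equal(t3$sequence, A)
  # omega = 0 never splits
  t4 <- denoise_dada(fake_derep(c(A, B), c(1000, 1000)),
                     dada_params(omega = 0))
  expect_equal(n_features(t4), 1)
  expect_equal(t4$sequence, A)
})

test_that("mixed-length input is denoised per length group", {
  set.seed(75)
  A <- random_dna(1, 100)
  C <- random_dna(1, 98)
  tab <- denoise_dada(fake_derep(c(A, C), c(800, 700)))
  expect_setequal(tab$sequence, c(A, C))
})
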