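test_that("zero-error reads reproduce their templates exactly", {
  refs <- generate_reference_set(3, 120, 15, seed = 4)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0,
                         depth_per_sample = 300)
  mix <- compose_sample(refs, NULL, des, 1)
  rp <- sequence_reads(mix, refs, NULL, perfect_model(read_len = 100),
                       300, seed = 5)
  al <- reference_alleles(refs)
  tpl <- setNames(al$sequence, al$template_id)
  expect_true(all(rp$fwd_seq == substr(tpl[rp$origin_id], 1, 100)))
  expect_true(all(rp$rev_seq ==
                    revcomp(substr(tpl[rp$origin_id], 21, 120))))
  expect_true(all(rp$n_substitutions == 0))
  # merged sequences recover exactly the sampled template set
  merged <- merge_pairs(rp, preprocess_params(head_trim = 0, trim_fwd = 100,
                                              trim_rev = 100,
                                              length_window = c(120, 120)))
  expect_setequal(unique(merged$sequence), unname(tpl[unique(rp$origin_id)]))
})

test_that("substitution counts match the binomial expectation", {
  refs <- generate_reference_set(1, 100, 1, seed = 8)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0,
                         depth_per_sample = 10000)
  mix <- compose_sample(refs, NULL, des, 1)
  em <- error_model(read_len = 100, mean_q_fwd = c(20, 20),
                    mean_q_rev = c(20, 20), sd_q = 0, chimera_rate = 0)
  rp <- sequence_reads(mix, refs, NULL, em, 10000, seed = 9)
  # 2 x 100 bases at Q20: expected 2 substitutions per pair; binomial oracle
  exp_subs <- 2 * 100 * 0.01
  sigma <- sqrt(2 * 100 * 0.01 * 0.99 / 10000)
  expect_lt(abs(mean(rp$n_substitutions) - exp_subs), 3 * sigma)
})

test_that("chimera generation hits the configured rate", {
  refs <- generate_reference_set(4, 100, 15, seed = 12)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0,
                         depth_per_sample = 10000)
  mix <- compose_sample(refs, NULL, des, 1)
  em <- error_model(read_len = 80, sd_q = 0, chimera_rate = 0.05,
                    substitution_prob = function(q) rep(0, length(q)))
  rp <- sequence_reads(mix, refs, NULL, em, 10000, seed = 13)
  n_chim <- sum(rp$origin_class == "chimera")
  sigma <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n_chim - 500), 3 * sigma)
  expect_true(all(grepl("^chimera:", rp$origin_id[rp$origin_class == "chimera"])))
})

test_that("quality strings stay within the Phred range and depth 0 fails", {
  refs <- generate_reference_set(1, 60, 1, seed = 2)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0)
  mix <- compose_sample(refs, NULL, des, 1)
  em <- error_model(read_len = 60, mean_q_fwd = c(41, 2),
                    mean_q_rev = c(41, 2), sd_q = 10)
  rp <- sequence_reads(mix, refs, NULL, em, 200, seed = 3)
  q <- unlist(lapply(rp$fwd_qual, function(s) utf8ToInt(s) - 33L))
  expect_true(all(q >= 2 & q <= 41))
  expect_error(sequence_reads(mix, refs, NULL, em, 0, seed = 3))
})

test_that("FASTQ output round-trips byte-identically", {
  refs <- generate_reference_set(2, 120, 15, seed = 6)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0,
                         depth_per_sample = 50)
  mix <- compose_sample(refs, NULL, des, 1)
  em <- error_model(read_len = 100)
  rp <- sequence_reads(mix, refs, NULL, em, 50, seed = 7)
  dir <- tempfile(); dir.create(dir)
  paths <- write_sample_fastq(rp, dir, "s1")
  back <- read_fastq_pairs(paths[1], paths[2])
  expect_identical(back$fwd_seq, rp$fwd_seq)
  expect_identical(back$fwd_qual, rp$fwd_qual)
  expect_identical(back$rev_seq, rp$rev_seq)
  expect_identical(back$rev_qual, rp$rev_qual)
  # writing the same simulation twice gives identical files
  rp2 <- sequence_reads(mix, refs, NULL, em, 50, seed = 7)
  paths2 <- write_sample_fastq(rp2, dir, "s2")
  expect_identical(readLines(paths[1])[-seq(1, 200, 4)],
                   readLines(paths2[1])[-seq(1, 200, 4)])
})

test_that("the error model constructor enforces its invariants", {
  expect_error(error_model(chimera_rate = 1))
  expect_error(error_model(substitution_prob = function(q) q / 100),
               "non-increasing")
})
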