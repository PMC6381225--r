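test_that("trimming removes head cycles and 3' tails in lockstep", {
  tpl <- random_dna(1, 251)
  p <- make_pair(tpl, tpl, q_fwd = 25L, q_rev = 30L)
  pr <- preprocess_params(head_trim = 15, trim_fwd = 230, trim_rev = 210)
  out <- trim_reads(p, pr)
  expect_equal(nchar(out$fwd_seq), 215)   # cycles 16..230
  expect_equal(nchar(out$rev_seq), 195)   # cycles 16..210
  expect_equal(out$fwd_seq, substr(tpl, 16, 230))
  expect_equal(nchar(out$fwd_qual), 215)
  expect_equal(attr(out, "dropped_trim"), 0)

  # identity trim
  id <- trim_reads(p, preprocess_params(head_trim = 0, trim_fwd = 251,
                                        trim_rev = 251))
  expect_equal(id$fwd_seq, tpl)

  # degenerate window: read dropped and counted
  deg <- trim_reads(p, preprocess_params(head_trim = 15, trim_fwd = 10,
                                         trim_rev = 210))
  expect_equal(nrow(deg), 0)
  expect_equal(attr(deg, "dropped_trim"), 1)
})

test_that("pair merging picks the best ungapped overlap", {
  set.seed(21)
  tpl <- random_dna(1, 40)
  # fwd = first 30, rev = rc of last 30 -> true overlap 20
  p <- make_pair(substr(tpl, 1, 30), revcomp(substr(tpl, 11, 40)),
                 q_fwd = 20L, q_rev = 20L)
  pr <- preprocess_params(head_trim = 0, trim_fwd = 30, trim_rev = 30,
                          min_overlap = 16, length_window = c(40, 40))
  m <- merge_pairs(p, pr)
  expect_equal(nchar(m$sequence), 30 + 30 - 20)
  expect_equal(m$sequence, tpl)
  # agreeing Q20+Q20 overlap bases get posterior error 1e-4 -> Phred 40
  q <- utf8ToInt(m$quality) - 33L
  expect_true(all(q[11:30] == 40))
  expect_true(all(q[1:10] == 20))
})

test_that("overlaps beyond the mismatch budget are discarded", {
  set.seed(22)
  tpl <- random_dna(1, 100)
  fwd <- substr(tpl, 1, 70)
  rev_tpl <- substr(tpl, 31, 100)          # overlap 40 with fwd
  rev_bad <- sub_at(rev_tpl, 1:11)         # 11 mismatches in the overlap
  pr <- preprocess_params(head_trim = 0, trim_fwd = 70, trim_rev = 70,
                          max_merge_diffs = 10, min_overlap = 30)
  m <- merge_pairs(make_pair(fwd, revcomp(rev_bad)), pr)
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "dropped_merge"), 1)
  # 10 mismatches are still tolerated
  rev_ok <- sub_at(rev_tpl, 1:10)
  m2 <- merge_pairs(make_pair(fwd, revcomp(rev_ok)), pr)
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "dropped_merge"), 0)
})

test_that("disagreeing overlap bases keep the higher-quality base", {
  set.seed(23)
  tpl <- random_dna(1, 40)
  rev_seq <- sub_at(tpl, 20)                 # disagreement inside overlap
  p <- make_pair(substr(tpl, 1, 30), revcomp(substr(rev_seq, 11, 40)),
                 q_fwd = 35L, q_rev = 20L)
  pr <- preprocess_params(head_trim = 0, trim_fwd = 30, trim_rev = 30,
                          min_overlap = 16)
  m <- merge_pairs(p, pr)
  expect_equal(substr(m$sequence, 20, 20), substr(tpl, 20, 20)) # Q35 wins
  # posterior error e_hi/(e_hi+e_lo) with e=10^-3.5 vs 10^-2
  e_hi <- 10^-3.5; e_lo <- 10^-2
  q_exp <- round(-10 * log10(e_hi / (e_hi + e_lo)))
  expect_equal(utf8ToInt(substr(m$quality, 20, 20)) - 33L, q_exp)
})

test_that("length and expected-error filters apply their thresholds", {
  recs <- fake_merged(c(random_dna(1, 222), random_dna(1, 226),
                        random_dna(1, 220), random_dna(1, 219)),
                      c(1, 1, 1, 1))
  pr <- preprocess_params(length_window = c(220, 225))
  out <- length_filter(recs, pr)
  expect_equal(sort(nchar(out$sequence)), c(220, 222))
  expect_equal(attr(out, "dropped_length"), 2)

  # EE arithmetic: 100 bases at Q20 -> EE 1.0; 300 -> 3.0
  r100 <- fake_merged(random_dna(1, 100), 1, q = 20L)
  r300 <- fake_merged(random_dna(1, 300), 1, q = 20L)
  expect_equal(expected_errors(r100$quality), 1.0, tolerance = 1e-9)
  expect_equal(expected_errors(r300$quality), 3.0, tolerance = 1e-9)
  expect_equal(nrow(expected_error_filter(r100, 2)), 1)
  expect_equal(nrow(expected_error_filter(r300, 2)), 0)
  expect_equal(nrow(expected_error_filter(r300, Inf)), 1)
  expect_error(expected_errors(""), "empty quality")
})

test_that("the expected-error filter is monotone in its threshold", {
  set.seed(31)
  refs <- generate_reference_set(2, 150, 15, seed = 31)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0,
                         depth_per_sample = 400)
  mix <- compose_sample(refs, NULL, des, 1)
  em <- error_model(read_len = 120, mean_q_fwd = c(35, 12),
                    mean_q_rev = c(35, 12))
  rp <- sequence_reads(mix, refs, NULL, em, 400, seed = 32)
  pr <- preprocess_params(head_trim = 0, trim_fwd = 120, trim_rev = 120,
                          length_window = c(150, 150))
  merged <- length_filter(merge_pairs(rp, pr), pr)
  kept <- lapply(c(3, 2, 1, 0.5), function(t) {
    expected_error_filter(merged, t)$read_id
  })
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("dereplication orders by abundance then sequence and conserves counts", {
  recs <- fake_merged(c("AAAA", "CCCC"), c(2, 1))
  d <- dereplicate(recs)
  expect_equal(d$sequence, c("AAAA", "CCCC"))
  expect_equal(d$abundance, c(2L, 1L))

  # tie broken lexicographically, stable across input order
  r1 <- fake_merged(c("TTTT", "AAAA"), c(3, 3))
  r2 <- fake_merged(c("AAAA", "TTTT"), c(3, 3))
  expect_identical(dereplicate(r1)$sequence, c("AAAA", "TTTT"))
  expect_identical(dereplicate(r1), dereplicate(r2))

  # pooled scope conserves per-sample counts
  pooled <- dereplicate(list(s1 = fake_merged(c("AAAA", "CCCC"), c(2, 1)),
                             s2 = fake_merged(c("AAAA", "GGGG"), c(4, 2))))
  expect_equal(colnames(pooled$counts), c("s1", "s2"))
  expect_equal(pooled$counts[pooled$sequence == "AAAA", ],
               c(s1 = 2L, s2 = 4L))
  expect_equal(sum(pooled$counts), 9)
})

test_that("preprocessing keeps a conserving read ledger on both branches", {
  refs <- generate_reference_set(4, 253, 20, seed = 41)
  ctm <- generate_contaminant_pool(3, 253, refs, seed = 42)
  des <- dilution_design(n_samples = 1, contaminant_mass = 0.01,
                         depth_per_sample = 600)
  mix <- compose_sample(refs, ctm, des, 1)
  em <- error_model(mean_q_fwd = c(35, 15), mean_q_rev = c(33, 12),
                    chimera_rate = 0.02)
  rp <- sequence_reads(mix, refs, ctm, em, 600, seed = 43)
  for (branch in c("merged", "dada")) {
    out <- preprocess_sample(rp, preprocess_params(), branch = branch)
    led <- attr(out, "ledger")
    expect_equal(led[["input"]], 600)
    expect_equal(led[["input"]],
                 led[["output"]] + led[["dropped_trim"]] +
                   led[["dropped_merge"]] + led[["dropped_length"]] +
                   led[["dropped_ee"]])
    expect_equal(nrow(out), led[["output"]])
  }
})
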