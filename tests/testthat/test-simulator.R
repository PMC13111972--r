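test_that("template sampling honours the GC bias", {
  withr::with_seed(1, {
    s <- sample_sequence(200, 1.0)
    expect_true(all(strsplit(s, "")[[1]] %in% c("G", "C")))
    s2 <- sample_sequence(10000, 0.5)
    gc <- mean(strsplit(s2, "")[[1]] %in% c("G", "C"))
    expect_equal(gc, 0.5, tolerance = 0.04)
  })
  expect_identical(withr::with_seed(3, sample_sequence(50, 0.4)),
                   withr::with_seed(3, sample_sequence(50, 0.4)))
})

test_that("haplotype derivation deletes at 1/4 and 3/4 of the template", {
  h <- make_haplotypes("AACCGGTT")
  expect_identical(h$hap1, "AACGGTT")
  expect_identical(h$hap2, "AACCGG")
  expect_error(make_haplotypes("ACGTACG"), "at least 8")
  withr::with_seed(2, {
    for (k in 1:10) {
      L <- sample(8:200, 1)
      h <- make_haplotypes(sample_sequence(L, 0.4))
      expect_identical(nchar(h$hap1) - nchar(h$hap2), 1L)
      expect_identical(nchar(h$hap1), L - 1L)
    }
  })
})

test_that("mixing superposes the haplotypes from both ends", {
  m <- mix_traces("AACGGTT", "AACCGG")
  expect_identical(m$fwd, "AACSGKT")
  expect_identical(m$rev_raw, "MMSSKTT")  # reverse-complement of AAMSSKK
  same <- mix_traces("ACGT", "ACGT")
  expect_identical(same$fwd, "ACGT")
  expect_identical(same$rev_raw, reverse_complement("ACGT"))
})

test_that("error injection follows the 16-outcome model", {
  expect_identical(apply_errors("ACGTACGT", 0), "ACGTACGT")
  withr::with_seed(4, {
    n <- 20000
    out <- strsplit(apply_errors(strrep("A", n), 1), "")[[1]]
    # at rate 1 a position stays A via "no change" (1/16) or redrawing A (1/16)
    expect_equal(mean(out == "A"), 2 / 16, tolerance = 0.02)
    # all 15 codes are reachable
    expect_setequal(unique(out), iupac_codes())
  })
  expect_identical(withr::with_seed(5, apply_errors(strrep("ACGT", 20), 0.5)),
                   withr::with_seed(5, apply_errors(strrep("ACGT", 20), 0.5)))
})

test_that("a trial's true offsets are the padding and padding + 1", {
  tr <- run_trial(length = 80, gc = 0.4, error_rate = 0.05, padding = 100, seed = 9)
  expect_identical(tr$true_offsets, c(100L, 101L))
  tr2 <- run_trial(length = 80, gc = 0.4, error_rate = 0.05, padding = 100, seed = 9)
  expect_identical(tr$detected, tr2$detected)
  expect_identical(tr$fwd, tr2$fwd)
})

test_that("at zero error both true offsets have fully compatible overlaps", {
  for (seed in 1:5) {
    tr <- run_trial(length = 60, gc = 0.35, error_rate = 0, padding = 100, seed = seed)
    for (o in tr$true_offsets) {
      expect_identical(score_offset(tr$fwd, tr$rev, o)$n_mismatch, 0L)
    }
    expect_true(all(tr$success))
  }
})

test_that("out-of-range trial parameters warn but run", {
  expect_warning(run_trial(length = 20, gc = 0.4, error_rate = 0, seed = 1),
                 "outside the benchmarked range")
  expect_warning(run_trial(length = 50, gc = 0.9, error_rate = 0, seed = 1),
                 "GC fraction")
})

test_that("a study tabulates recovery proportions per cell and scheme", {
  st <- run_study(lengths = c(30, 60), gcs = 0.4, error_rates = c(0, 0.1),
                  reps = 5, seed = 42)
  expect_s3_class(st, "tp_study")
  expect_identical(nrow(st), 2L * 2L * 3L)
  expect_true(all(st$prop_correct >= 0 & st$prop_correct <= 1))
  expect_true(all(st$reps == 5L))
  st2 <- run_study(lengths = c(30, 60), gcs = 0.4, error_rates = c(0, 0.1),
                   reps = 5, seed = 42)
  expect_identical(st$prop_correct, st2$prop_correct)
})

test_that("recovery does not improve when the error rate rises", {
  st <- run_study(lengths = 100, gcs = 0.4, error_rates = c(0, 0.35),
                  schemes = "ambiguity_corrected", reps = 30, seed = 7)
  expect_gte(st$prop_correct[st$error_rate == 0],
             st$prop_correct[st$error_rate == 0.35] - 0.1)
})
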