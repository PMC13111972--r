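test_that("offset enumeration covers every alignment with enough overlap", {
  expect_identical(enumerate_offsets(3, 3, 1), -2:2)
  expect_identical(enumerate_offsets(1, 5, 1), 0:4)
  expect_identical(enumerate_offsets(4, 4, 4), 0L)
  expect_length(enumerate_offsets(3, 3, 4), 0)
})

test_that("the overlap-corrected score counts compatible positions minus overlap/4", {
  expect_equal(score_offset("ACGT", "ACGT", 0, "overlap_corrected")$score, 3.0)
  expect_equal(score_offset("ACGT", "ACGT", 3, "overlap_corrected")$score, -0.25)
  expect_equal(score_offset("ACGT", "TTTT", 0, "overlap_corrected")$score, 0.0)
})

test_that("the ambiguity-corrected score halves ambiguous matches", {
  expect_equal(score_offset("AW", "AA", 0, "ambiguity_corrected")$score, 1.0)
  expect_equal(score_offset("WW", "SS", 0, "ambiguity_corrected")$score, -0.5)
  expect_equal(score_offset("ACGT", "ACGT", 0, "ambiguity_corrected")$score, 3.0)
})

test_that("the longest-run score is the longest stretch of compatible positions", {
  expect_equal(score_offset("ACGTACGT", "ACGAACGT", 0, "longest_run")$score, 4)
  expect_equal(score_offset("AAAA", "TTTT", 0, "longest_run")$score, 0)
  expect_equal(score_offset("AR", "AG", 0, "longest_run")$score, 2)
})

test_that("no alignment at an offset with zero overlap", {
  expect_error(score_offset("ACGT", "ACGT", 10), "No alignment")
})

test_that("ranking on the bundled worked pair reproduces the reference values", {
  fwd <- example_fwd(); rev <- example_rev()
  # expected values frozen from an independent brute-force scorer
  rkA <- rank_offsets(fwd, rev, "overlap_corrected")
  expect_identical(rkA$offset[1:2], c(0L, 1L))
  expect_equal(rkA$score[1:2], c(24.75, 24.0))
  expect_identical(rkA$n_mismatch[1:2], c(0L, 0L))
  rkB <- rank_offsets(fwd, rev, "ambiguity_corrected")
  expect_identical(rkB$offset[1:2], c(0L, 1L))
  expect_equal(rkB$score[1:2], c(12.75, 12.0))
  rkC <- rank_offsets(fwd, rev, "longest_run")
  expect_identical(rkC$offset[1:2], c(0L, 1L))
  expect_equal(rkC$score[1:2], c(33, 32))
  # one row per enumerable offset
  expect_identical(nrow(rkA), nchar(fwd) + nchar(rev) - 1L)
})

test_that("a self-alignment ranks offset zero first under every scheme", {
  for (sc in all_schemes) {
    expect_identical(rank_offsets("ACGT", "ACGT", sc)$offset[1], 0L)
  }
})

test_that("ranking order is total: score desc, mismatches asc, |offset| asc", {
  set.seed(11)
  for (k in 1:20) {
    rk <- rank_offsets(random_iupac(20), random_iupac(25),
                       sample(all_schemes, 1))
    key_prev <- NULL
    for (i in seq_len(nrow(rk))) {
      key <- c(-rk$score[i], rk$n_mismatch[i], abs(rk$offset[i]), rk$offset[i])
      if (!is.null(key_prev)) {
        cmp <- key - key_prev
        first <- cmp[which(cmp != 0)[1]]
        expect_true(is.na(first) || first > 0)
      }
      key_prev <- key
    }
  }
})

test_that("scores are symmetric under swapping sequences and negating the offset", {
  set.seed(5)
  for (k in 1:25) {
    f <- random_iupac(sample(5:25, 1))
    r <- random_iupac(sample(5:25, 1))
    o <- sample(enumerate_offsets(nchar(f), nchar(r)), 1)
    for (sc in all_schemes) {
      expect_equal(score_offset(f, r, o, sc)$score,
                   score_offset(r, f, -o, sc)$score)
    }
  }
})

test_that("without ambiguity codes the two corrected schemes coincide", {
  set.seed(9)
  for (k in 1:25) {
    f <- random_iupac(sample(5:30, 1), ambiguous = FALSE)
    r <- random_iupac(sample(5:30, 1), ambiguous = FALSE)
    a <- rank_offsets(f, r, "overlap_corrected")
    b <- rank_offsets(f, r, "ambiguity_corrected")
    expect_equal(a$score[order(a$offset)], b$score[order(b$offset)])
  }
})

test_that("scores respect their analytic upper bounds", {
  set.seed(13)
  for (k in 1:25) {
    f <- random_iupac(sample(5:30, 1))
    r <- random_iupac(sample(5:30, 1))
    for (sc in all_schemes) {
      rk <- rank_offsets(f, r, sc)
      if (sc == "longest_run") {
        expect_true(all(rk$score <= rk$overlap_len))
        expect_true(all(rk$score == round(rk$score)))
      } else {
        expect_true(all(rk$score <= 0.75 * rk$overlap_len))
      }
      expect_identical(rk$n_compatible + rk$n_mismatch, rk$overlap_len)
    }
  }
})

test_that("every scheme agrees with the naive pair-by-pair oracle", {
  set.seed(21)
  for (k in 1:30) {
    f <- random_iupac(sample(5:20, 1))
    r <- random_iupac(sample(5:20, 1))
    for (sc in all_schemes) {
      rk <- rank_offsets(f, r, sc)
      for (i in seq_len(nrow(rk))) {
        expect_identical(rk$score[i], oracle_score(f, r, rk$offset[i], sc))
      }
    }
  }
})
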