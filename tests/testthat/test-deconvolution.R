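test_that("consensus columns combine, copy and case-mark as specified", {
  expect_identical(as.character(build_consensus("ACGT", "ACGT", 0)), "ACGT")
  expect_identical(as.character(build_consensus("ACGT", "ACGTAA", 0)), "ACGTaa")
  c3 <- build_consensus("AYGT", "ACGT", 0)
  expect_identical(as.character(c3), "ACGT")  # intersect(Y, C) = C
  expect_length(c3$mismatch_columns, 0)
})

test_that("incompatible both-covered columns keep the union and are recorded", {
  cons <- build_consensus("AAAA", "AAAT", 0)
  expect_identical(as.character(cons), "AAAW")
  expect_identical(cons$mismatch_columns, 4L)
})

test_that("lowercase column count equals single-coverage column count", {
  set.seed(31)
  for (k in 1:20) {
    f <- random_iupac(sample(5:20, 1))
    r <- random_iupac(sample(5:20, 1))
    o <- sample(enumerate_offsets(nchar(f), nchar(r)), 1)
    cons <- build_consensus(f, r, o)
    rendered <- strsplit(as.character(cons), "")[[1]]
    expect_identical(sum(rendered %in% letters), sum(cons$support != "both"))
    expect_length(rendered, max(nchar(r), nchar(f) + o) - min(0, o))
  }
})

test_that("mutual explanation resolves a double peak via the other haplotype", {
  # mixing haplotypes AAGTACGT and ACCGTAT gives the traces below; the
  # forward S at position 3 resolves to G in one haplotype because the other
  # is already explained by the C (frozen with the independent oracle)
  res <- resolve_haplotypes("AMSKWMKT", "AASYRYRT", 0, 1)
  res <- check_consistency("AMSKWMKT", "AASYRYRT", res)
  hs <- haplotype_strings(res)
  expect_identical(hs[["hap1"]], "AAGTACGT")
  expect_identical(hs[["hap2"]], "aACCGTATt")
  expect_identical(res$n_check_mismatches, 0L)
  expect_length(res$unresolved$hap1, 0)
  expect_length(res$unresolved$hap2, 0)
})

test_that("a single peak shared by both haplotypes stays in both", {
  res <- resolve_haplotypes("AAA", "AAAA", 0, 1)
  # frames span the reverse coordinates; single-covered tails are lowercase
  expect_identical(haplotype_strings(res)[["hap1"]], "AAAa")
  expect_identical(haplotype_strings(res)[["hap2"]], "aAAA")
  expect_identical(nrow(res$resolution_warnings), 0L)
})

test_that("a peak the two-haplotype model cannot explain raises a warning", {
  # forward position 2 observes H = {A,C,T}; after resolution one haplotype
  # explains at most one base, leaving two bases for the other
  res <- resolve_haplotypes("AHAA", "ACAAA", 0, 1)
  expect_gt(nrow(res$resolution_warnings), 0)
})

test_that("identical offsets are refused", {
  expect_error(resolve_haplotypes("ACGT", "ACGT", 1, 1), "distinct")
})

test_that("the remix check flags positions the reconstruction cannot produce", {
  tr <- run_trial(length = 60, gc = 0.4, error_rate = 0, padding = 0, seed = 5)
  res <- check_consistency(tr$fwd, tr$rev, resolve_haplotypes(tr$fwd, tr$rev, 0, 1))
  expect_identical(res$n_check_mismatches, 0L)
  expect_identical(res$n_check_mismatches, nrow(res$warnings))
  # corrupt one observed character: the remix can no longer reproduce it
  bad <- paste0("B", substr(tr$fwd, 2, nchar(tr$fwd)))
  res2 <- check_consistency(bad, tr$rev, resolve_haplotypes(bad, tr$rev, 0, 1))
  expect_gt(res2$n_check_mismatches, 0)
  expect_identical(res2$n_check_mismatches, nrow(res2$warnings))
})

test_that("possibility sets only shrink and the fixpoint ignores sweep order", {
  set.seed(17)
  for (k in 1:10) {
    tr <- run_trial(length = sample(30:80, 1), gc = 0.4, error_rate = 0.05,
                    padding = 0, seed = 1000 + k)
    a <- resolve_haplotypes(tr$fwd, tr$rev, 0, 1, sweep_order = "forward_first")
    b <- resolve_haplotypes(tr$fwd, tr$rev, 0, 1, sweep_order = "reverse_first")
    expect_identical(a$hap1, b$hap1)
    expect_identical(a$hap2, b$hap2)
    # every resolved column is a subset of its consensus column
    cons1 <- build_consensus(tr$fwd, tr$rev, 0)
    expect_true(all(bitwAnd(a$hap1, cons1$code) == a$hap1))
  }
})

test_that("offset-pair exploration evaluates all pairs and sorts by mismatches", {
  fwd <- example_fwd(); rev <- example_rev()
  ranked <- rank_offsets(fwd, rev, "ambiguity_corrected")
  tab <- explore_offset_pairs(fwd, rev, ranked, k = 5)
  expect_identical(nrow(tab), 10L)
  expect_true(all(diff(tab$n_check_mismatches) >= 0))
  # the top-ranked pair also minimises the remix mismatches (frozen: 0)
  expect_identical(sort(c(tab$o1[1], tab$o2[1])), c(0L, 1L))
  expect_identical(tab$n_check_mismatches[1], 0L)
})

test_that("k = 2 reduces to the default top pair", {
  fwd <- example_fwd(); rev <- example_rev()
  ranked <- rank_offsets(fwd, rev, "ambiguity_corrected")
  tab <- explore_offset_pairs(fwd, rev, ranked, k = 2)
  expect_identical(nrow(tab), 1L)
  expect_identical(c(tab$o1, tab$o2), ranked$offset[1:2])
})

test_that("tidy and glance summarise a reconstruction", {
  res <- resolve_haplotypes("AMSKWMKT", "AASYRYRT", 0, 1)
  res <- check_consistency("AMSKWMKT", "AASYRYRT", res)
  td <- tidy(res)
  expect_identical(nrow(td), length(res$hap1) + length(res$hap2))
  g <- glance(res)
  expect_identical(g$n_check_mismatches, 0L)
  expect_identical(g$offset1, 0L)
})
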