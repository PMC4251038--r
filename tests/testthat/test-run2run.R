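test_that("cross-run overlap is identity-or-containment, count-weighted", {
  part <- cross_overlap(mk_uniques(c(ACGTACGT = 3L)),
                        mk_uniques(c(GTAC = 5L)))
  expect_equal(part$run1$n_unique_overlap, 1L)
  expect_equal(part$run2$n_unique_overlap, 1L)
  expect_equal(part$run1$n_total_overlap, 3L)
  expect_equal(part$run2$n_total_overlap, 5L)
  expect_equal(part$n_unique_overlap_both, 1L)

  # disjoint sets: zero overlap
  part2 <- cross_overlap(mk_uniques(c(AAAA = 2L)), mk_uniques(c(CCCC = 3L)))
  expect_equal(part2$run1$n_unique_overlap, 0L)
  expect_equal(part2$run2$n_total_overlap, 0L)
  expect_equal(part2$n_unique_overlap_both, 0L)

  # identical equal-length sets: all three overlap counts agree
  u <- mk_uniques(c(ACGT = 2L, TTTT = 1L))
  part3 <- cross_overlap(u, u)
  expect_equal(part3$run1$n_unique_overlap, 2L)
  expect_equal(part3$run2$n_unique_overlap, 2L)
  expect_equal(part3$n_unique_overlap_both, 2L)
})

test_that("cross-run overlap matches the brute-force oracle on random sets", {
  set.seed(51)
  for (rep in 1:40) {
    a <- dedup(random_bases(sample(1:100, 1)))$uniques
    b <- dedup(random_bases(sample(1:100, 1)))$uniques
    part <- cross_overlap(a, b)
    want_a <- oracle_cross_overlap(a$sequence, b$sequence)
    want_b <- oracle_cross_overlap(b$sequence, a$sequence)
    expect_equal(part$run1$n_unique_overlap, sum(want_a))
    expect_equal(part$run2$n_unique_overlap, sum(want_b))
    expect_equal(part$run1$n_total_overlap, sum(a$count[want_a]))
    expect_equal(part$run2$n_total_overlap, sum(b$count[want_b]))
    # partition conservation, totals and uniques
    expect_equal(part$run1$n_unique_overlap +
                   nrow(part$run1$non_overlapping), nrow(a))
    expect_equal(part$run1$n_total_overlap +
                   sum(part$run1$non_overlapping$count), sum(a$count))
  }
})

test_that("merging both runs' overlapping uniques collapses containment", {
  # equal-length identical sets: union count equals either side
  u <- mk_uniques(c(ACGT = 1L, GGGG = 1L))
  expect_equal(merge_overlap_union(u, u), 2L)

  # containment across runs collapses onto the longer sequence
  expect_equal(merge_overlap_union(mk_uniques(c(ACGTAC = 1L)),
                                   mk_uniques(c(CGTA = 1L))), 1L)

  # disjoint overlapping sets simply add up
  expect_equal(merge_overlap_union(mk_uniques(c(AAAA = 1L)),
                                   mk_uniques(c(CCCC = 1L))), 2L)

  expect_equal(merge_overlap_union(mk_uniques(integer(0)),
                                   mk_uniques(integer(0))), 0L)
})

test_that("variable-length sets can have more merged uniques than either run", {
  # Y=AAAA sits in both X1 and X2 (run1); W=TTTT sits in both Z1 and Z2
  # (run2): every unique overlaps, the merge absorbs Y and W, and the four
  # containers survive -- 4 > 3 on both sides.
  a <- mk_uniques(c(CAAAAC = 1L, GAAAAG = 1L, TTTT = 1L))
  b <- mk_uniques(c(AAAA = 1L, CTTTTC = 1L, GTTTTG = 1L))
  part <- cross_overlap(a, b)
  expect_equal(part$run1$n_unique_overlap, 3L)
  expect_equal(part$run2$n_unique_overlap, 3L)
  expect_equal(part$n_unique_overlap_both, 4L)
})

test_that("derived statistics reproduce the printed two-run ledger", {
  out <- list(
    run1 = list(n_raw = 2000000, n_cleaned = 1968732,
                n_unique_identical_only = 1487552, n_unique_full = 1487552,
                n_total_overlap = 712022, n_unique_overlap = 360898),
    run2 = list(n_raw = 2000000, n_cleaned = 1997550,
                n_unique_identical_only = 1482834, n_unique_full = 1482834,
                n_total_overlap = 730780, n_unique_overlap = 360898),
    n_unique_overlap_both = 360898)
  d <- run2run_derived(out)
  expect_equal(d$run1$n_redundant_cleaned, 481180)
  expect_equal(d$run1$redundancy_rate_pct, 32.3)
  expect_equal(d$run1$n_total_nonoverlap, 1256710)
  expect_equal(d$run1$n_unique_nonoverlap, 1126654)
  expect_equal(d$run1$n_redundant_nonoverlap, 130056)
  expect_equal(d$run1$nonoverlap_redundancy_pct, 11.5)
  expect_equal(d$run1$n_redundant_overlap, 351124)
  expect_equal(d$run1$overlap_redundancy_pct, 97.3)
  expect_equal(d$run1$overlap_over_cleaned_pct, 36.2)
  expect_equal(d$run2$redundancy_rate_pct, 34.7)
  expect_equal(d$overlap_over_cleaned_both_pct, 36.4)

  # zero overlap: overlap-stratum rates are zero, non-overlap rates equal
  # the whole-run rates
  out0 <- list(
    run1 = list(n_raw = 100, n_cleaned = 100, n_unique_identical_only = 80,
                n_unique_full = 80, n_total_overlap = 0,
                n_unique_overlap = 0),
    run2 = list(n_raw = 50, n_cleaned = 50, n_unique_identical_only = 40,
                n_unique_full = 40, n_total_overlap = 0,
                n_unique_overlap = 0),
    n_unique_overlap_both = 0)
  d0 <- run2run_derived(out0)
  expect_equal(d0$run1$overlap_redundancy_pct, 0)
  expect_equal(d0$run1$nonoverlap_redundancy_pct,
               d0$run1$redundancy_rate_pct)
  expect_equal(d0$overlap_over_cleaned_both_pct, 0)

  # an impossible output block signals an upstream bug
  bad <- out
  bad$run1$n_total_overlap <- bad$run1$n_cleaned + 1
  expect_error(run2run_derived(bad), class = "consistency_error")
})

test_that("two-run workflow partitions reads and writes four unique tables", {
  a <- mk_clean(c("ACGTACGT", "ACGTACGT", "TTTTGGGG", "CCCCCCAA"))
  b <- mk_clean(c("GTAC", "GTAC", "GTAC", "TTTTGGGG", "AAAAAAAA"))
  out <- tempfile()
  st <- run2run_stats(a, b, out_dir = out)
  # run1: ACGTACGT overlaps (contains GTAC), TTTTGGGG identical across runs
  expect_equal(st$run1$n_unique_overlap, 2L)
  expect_equal(st$run1$n_total_overlap, 3L)
  expect_equal(st$run2$n_unique_overlap, 2L)
  expect_equal(st$run2$n_total_overlap, 4L)
  # conservation of the partition
  expect_equal(st$run1$n_total_overlap + st$run1$n_total_nonoverlap,
               st$run1$n_cleaned)
  expect_equal(st$run1$n_unique_overlap + st$run1$n_unique_nonoverlap,
               st$run1$n_unique_full)
  for (f in c("run1_overlapping.tsv", "run1_non_overlapping.tsv",
              "run2_overlapping.tsv", "run2_non_overlapping.tsv",
              "run2run_stats.tsv"))
    expect_true(file.exists(file.path(out, f)))

  # identical inputs: everything overlaps
  st2 <- run2run_stats(a, a)
  expect_equal(st2$run1$n_unique_overlap, st2$run1$n_unique_full)
  expect_equal(st2$run1$n_total_overlap, st2$run1$n_cleaned)
  expect_equal(nrow(st2$partition$run1$non_overlapping), 0)
})

test_that("swapping run order permutes columns and fixes shared quantities", {
  set.seed(52)
  a <- mk_clean(random_bases(60))
  b <- mk_clean(random_bases(80))
  st <- run2run_stats(a, b)
  sw <- run2run_stats(b, a)
  expect_equal(st$run1[names(st$run1)], sw$run2[names(st$run1)])
  expect_equal(st$run2[names(st$run2)], sw$run1[names(st$run2)])
  expect_equal(st$n_unique_overlap_both, sw$n_unique_overlap_both)
  expect_equal(st$overlap_over_cleaned_both_pct,
               sw$overlap_over_cleaned_both_pct)
})
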