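test_that("CIGAR walking covers M/=/X, skips with D/N, ignores I/S/H/P", {
  civ <- cigar_reference_intervals(11L, "5M")
  expect_equal(unname(civ$intervals), cbind(10L, 15L))  # 1-based 11..15
  expect_equal(civ$span, 5L)

  civ2 <- cigar_reference_intervals(1L, "3M2D3M")
  expect_equal(unname(civ2$intervals), cbind(c(0L, 5L), c(3L, 8L)))
  expect_equal(civ2$span, 8L)

  civ3 <- cigar_reference_intervals(1L, "3M2I3M")
  expect_equal(unname(civ3$intervals), cbind(c(0L, 3L), c(3L, 6L)))
  expect_equal(civ3$span, 6L)

  civ4 <- cigar_reference_intervals(5L, "2S3=1X2N4M5H")
  expect_equal(civ4$span, 10L)

  expect_error(cigar_reference_intervals(1L, "*"), class = "cigar_parse_error")
  expect_error(cigar_reference_intervals(1L, "5Q"), class = "cigar_parse_error")
  expect_error(cigar_reference_intervals(1L, "M5"), class = "cigar_parse_error")
})

test_that("depth accumulation counts primary mapped records once per base", {
  scaffolds <- data.frame(name = "s1", length = 10L, sequence = NA,
                          stringsAsFactors = FALSE)
  aln <- data.frame(flag = c(0L, 0L), rname = "s1", pos = c(1L, 3L),
                    cigar = "5M", usable = TRUE, stringsAsFactors = FALSE)
  acc <- accumulate_depth(aln, scaffolds)
  expect_equal(acc$depths$s1, c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(acc$n_reads_mapped, 2L)

  only_unmapped <- data.frame(flag = 4L, rname = "*", pos = 0L, cigar = "*",
                              usable = FALSE, stringsAsFactors = FALSE)
  acc2 <- accumulate_depth(only_unmapped, scaffolds)
  expect_true(all(acc2$depths$s1 == 0L))
  expect_equal(acc2$n_reads_mapped, 0L)

  # secondary and supplementary records are excluded
  aln3 <- data.frame(flag = c(0L, 256L, 2048L), rname = "s1", pos = 1L,
                     cigar = "4M", usable = TRUE, stringsAsFactors = FALSE)
  acc3 <- accumulate_depth(aln3, scaffolds)
  expect_equal(acc3$n_reads_mapped, 1L)
  expect_equal(max(acc3$depths$s1), 1L)

  # alignment past scaffold end is an error naming the record
  over <- data.frame(flag = 0L, rname = "s1", pos = 8L, cigar = "5M",
                     usable = TRUE, stringsAsFactors = FALSE)
  expect_error(accumulate_depth(over, scaffolds),
               class = "coverage_out_of_bounds_error")
})

test_that("interval accumulation equals the naive per-base oracle", {
  set.seed(41)
  for (rep in 1:40) {
    inst <- random_alignment_instance()
    got <- accumulate_depth(inst$alignments, inst$scaffolds)
    want <- oracle_depth(inst$alignments, inst$scaffolds)
    expect_equal(got$depths, want$depths)
    expect_equal(got$n_reads_mapped, want$n_reads_mapped)
    # conservation: total depth equals the records' covered reference bases
    expect_equal(sum(vapply(got$depths, sum, 0)),
                 sum(vapply(want$depths, sum, 0)))
  }
})

test_that("coverage summary reproduces scaffold and mapping ratios", {
  # 5,191 unit scaffolds of which 3,960 are covered: the covered/total ratio
  # printed for a published 5,191-scaffold draft genome
  n_tot <- 5191L; n_cov <- 3960L
  scaffolds <- data.frame(name = paste0("s", seq_len(n_tot)), length = 1L,
                          sequence = NA, stringsAsFactors = FALSE)
  depths <- lapply(seq_len(n_tot), function(i) if (i <= n_cov) 1L else 0L)
  names(depths) <- scaffolds$name
  cov <- summarize_coverage(depths, scaffolds, n_cleaned = 7524261L,
                            n_reads_mapped = 6573572L)
  expect_equal(round(cov$summary$covered_scaffold_pct, 2), 76.29)
  expect_equal(round(cov$summary$mapped_over_cleaned_pct, 2), 87.37)
  expect_equal(cov$summary$n_scaffolds_covered, n_cov)

  # equal breadth everywhere: zero spread, evenness 0
  sc2 <- data.frame(name = c("a", "b"), length = 4L, sequence = NA,
                    stringsAsFactors = FALSE)
  cov2 <- summarize_coverage(list(a = rep(1L, 4), b = rep(2L, 4)), sc2)
  expect_equal(cov2$summary$evenness, 0)
  expect_equal(cov2$summary$genome_breadth_pct, 100)

  # one read covering one whole scaffold of two equal scaffolds:
  # breadth 50%, evenness sd/mean over {100, 0} = 1
  cov3 <- summarize_coverage(list(a = rep(1L, 4), b = rep(0L, 4)), sc2)
  expect_equal(cov3$summary$genome_breadth_pct, 50)
  expect_equal(cov3$summary$evenness, 1)

  expect_error(summarize_coverage(list(), scaffolds[0, ]),
               class = "coverage_error")
})

test_that("genome breadth is the length-weighted mean of scaffold breadths", {
  set.seed(42)
  for (rep in 1:10) {
    inst <- random_alignment_instance()
    acc <- accumulate_depth(inst$alignments, inst$scaffolds)
    cov <- summarize_coverage(acc$depths, inst$scaffolds)
    ps <- cov$per_scaffold
    expect_equal(cov$summary$genome_breadth_pct,
                 100 * sum(ps$covered_bases) / sum(ps$length))
    expect_equal(cov$summary$genome_depth,
                 sum(ps$mapped_bases) / sum(ps$length))
  }
})

test_that("evenness is scale-invariant", {
  sc <- data.frame(name = c("a", "b", "c"), length = c(10L, 20L, 40L),
                   sequence = NA, stringsAsFactors = FALSE)
  depths <- list(a = c(rep(1L, 5), rep(0L, 5)),
                 b = c(rep(3L, 10), rep(0L, 10)),
                 c = rep(0L, 40))
  e1 <- summarize_coverage(depths, sc)$summary$evenness
  # double every scaffold length and its covered run: breadths unchanged
  sc2 <- transform(sc, length = length * 2L)
  depths2 <- lapply(depths, function(d) rep(d, each = 2L))
  e2 <- summarize_coverage(depths2, sc2)$summary$evenness
  expect_equal(e1, e2)
})

test_that("breadth and depth histograms follow open-low/closed-high bins", {
  ps <- data.frame(breadth_pct = c(0, 40, 30.0001, 100, 0.5),
                   depth_mean = c(0, 1, 1.5, 10, 11))
  h <- bin_distributions(ps)
  b <- structure(h$breadth$n_scaffolds, names = h$breadth$bin)
  expect_equal(unname(b["0"]), 1L)
  expect_equal(unname(b["(30,40]"]), 2L)  # breadth 40 and 30.0001
  expect_equal(unname(b["(90,100]"]), 1L)
  expect_equal(unname(b["(0,10]"]), 1L)
  d <- structure(h$depth$n_scaffolds, names = h$depth$bin)
  expect_equal(unname(d["0"]), 1L)
  expect_equal(unname(d["(0,1]"]), 1L)    # depth 1 closed at the high end
  expect_equal(unname(d["(1,2]"]), 1L)
  expect_equal(unname(d["(4,10]"]), 1L)
  expect_equal(unname(d["(10,Inf)"]), 1L)
  # conservation
  expect_equal(sum(h$breadth$n_scaffolds), nrow(ps))
  expect_equal(sum(h$depth$n_scaffolds), nrow(ps))
})

test_that("exact-match aligner reports every forward occurrence", {
  ref <- data.frame(name = c("s1", "s2"), length = c(12L, 8L),
                    sequence = c("ACGTACGTAAAA", "TTTTACGT"),
                    stringsAsFactors = FALSE)
  # read equal to a scaffold prefix
  a1 <- exact_match_align("ACGTACGT", ref)
  expect_equal(a1$pos[1], 1L)
  expect_equal(a1$cigar[1], "8M")
  expect_equal(a1$flag[1], 0L)

  # absent read is flagged unmapped
  a2 <- exact_match_align("GGGGGGG", ref)
  expect_equal(a2$flag, 4L)
  expect_false(a2$usable)

  # read occurring twice: one primary, one secondary, reference order
  a3 <- exact_match_align("ACGT", ref)
  expect_equal(a3$flag, c(0L, 256L, 256L))
  expect_equal(a3$rname, c("s1", "s1", "s2"))
  expect_equal(a3$pos, c(1L, 5L, 5L))
})

test_that("run2ref composes alignment, accumulation, binning and outputs", {
  fx <- make_synthetic_run(seed = 9)
  clean <- preprocess_run(fx$reads)
  out <- tempfile()
  res <- run2ref(clean, fx$reference, out_dir = out)
  expect_equal(res$summary$n_scaffolds_covered, 10L)
  expect_equal(res$summary$n_reads_mapped, 1000L)
  expect_equal(sum(res$histograms$breadth$n_scaffolds), 10)
  for (f in c("per_scaffold.tsv", "coverage_summary.tsv", "depth_track.tsv",
              "breadth_histogram.tsv", "depth_histogram.tsv"))
    expect_true(file.exists(file.path(out, f)))

  # empty SAM: zero coverage everywhere
  sam <- tempfile(fileext = ".sam")
  writeLines("@SQ\tSN:s1\tLN:50", sam)
  res2 <- run2ref(sam = sam)
  expect_equal(res2$summary$genome_breadth_pct, 0)
  expect_equal(res2$summary$genome_depth, 0)
  expect_equal(res2$summary$n_scaffolds_covered, 0L)
})
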