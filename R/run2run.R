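#' Cross-run overlap of unique sequence sets
#'
#' A unique sequence of one run is *overlapping* when it is identical to, an
#' exact substring of, or an exact superstring of some unique sequence of the
#' other run; otherwise it is non-overlapping. Overlap totals are
#' count-weighted: the cleaned-read mass carried by the overlapping uniques.
#'
#' @param uniquesA,uniquesB Unique tables (data frames with `sequence`,
#'   `length`, `count`), each substring-free within itself.
#' @param strand `"forward"` or `"both"`.
#' @return List of class `overlap_partition` with, per run: `overlapping`
#'   and `non_overlapping` unique tables, `n_unique_overlap`,
#'   `n_total_overlap`; plus `n_unique_overlap_both` (unique overlapping
#'   sequences after merging both runs' overlapping sets).
#' @export
cross_overlap <- function(uniquesA, uniquesB, strand = "forward") {
  overl_A <- overlaps_other(uniquesA$sequence, uniquesB$sequence, strand)
  overl_B <- overlaps_other(uniquesB$sequence, uniquesA$sequence, strand)
  partA <- list(overlapping = uniquesA[overl_A, , drop = FALSE],
                non_overlapping = uniquesA[!overl_A, , drop = FALSE])
  partB <- list(overlapping = uniquesB[overl_B, , drop = FALSE],
                non_overlapping = uniquesB[!overl_B, , drop = FALSE])
  structure(list(
    run1 = c(partA, list(n_unique_overlap = sum(overl_A),
                         n_total_overlap = sum(uniquesA$count[overl_A]))),
    run2 = c(partB, list(n_unique_overlap = sum(overl_B),
                         n_total_overlap = sum(uniquesB$count[overl_B]))),
    n_unique_overlap_both = merge_overlap_union(
      partA$overlapping, partB$overlapping, strand)),
    class = "overlap_partition")
}

# For each sequence in `a`: is it identical to, a substring of, or a
# superstring of any sequence in `b`?
overlaps_other <- function(a, b, strand) {
  if (length(a) == 0) return(logical(0))
  if (length(b) == 0) return(rep(FALSE, length(a)))
  vapply(a, function(s)
    any(contained_in(s, b, strand)) || any(contained_in_rev(b, s, strand)),
    logical(1), USE.NAMES = FALSE)
}

# Which of `needles` are contained in the single string `haystack`?
contained_in_rev <- function(needles, haystack, strand) {
  hits <- stringi::stri_detect_fixed(haystack, needles)
  if (strand == "both")
    hits <- hits | stringi::stri_detect_fixed(haystack, revcomp(needles))
  hits
}

#' Count unique overlapping sequences across both runs
#'
#' Takes the union of the two runs' overlapping unique sets, merges cross-run
#' identical sequences and collapses cross-run inclusive sequences onto their
#' longest container, and returns the number of survivors. For equal-length
#' read sets this equals either run's overlapping count; for variable-length
#' sets it can exceed both.
#'
#' @param overlapA,overlapB Overlapping unique tables of the two runs.
#' @param strand `"forward"` or `"both"`.
#' @return Integer count of unique overlapping sequences from both runs.
#' @export
merge_overlap_union <- function(overlapA, overlapB, strand = "forward") {
  seqs <- c(overlapA$sequence, overlapB$sequence)
  if (length(seqs) == 0) return(0L)
  counts <- structure(rep(1L, length(unique(seqs))), names = unique(seqs))
  remove_inclusive(counts, strand)$n_unique
}

#' Run-to-run comparison workflow
#'
#' Compares two cleaned sequencing runs: deduplicates each independently
#' (identical, then inclusive reads), partitions each run's unique set into
#' overlapping and non-overlapping sequences against the other run, and
#' reports the full output and derived statistics ledger, including the
#' redundancy rates within each run and within the overlapping and
#' non-overlapping strata.
#'
#' @param cleanA,cleanB `clean_read_set` objects for Run1 and Run2.
#' @param out_dir Directory for the statistics table and the four unique
#'   tables (overlapping/non-overlapping for each run), or `NULL`.
#' @param strand `"forward"` or `"both"`.
#' @return Object of class `run2run_stats`: list with `run1`, `run2` (each a
#'   list of output and derived counters), `n_unique_overlap_both`,
#'   `overlap_over_cleaned_both_pct` and `partition`.
#' @export
run2run_stats <- function(cleanA, cleanB, out_dir = NULL,
                          strand = "forward") {
  d1 <- dedup(cleanA$reads$bases, strand)
  d2 <- dedup(cleanB$reads$bases, strand)
  part <- cross_overlap(d1$uniques, d2$uniques, strand)
  out <- list(
    run1 = run_output_block(cleanA, d1, part$run1),
    run2 = run_output_block(cleanB, d2, part$run2),
    n_unique_overlap_both = part$n_unique_overlap_both)
  stats <- run2run_derived(out)
  stats$partition <- part
  class(stats) <- "run2run_stats"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_unique_table(part$run1$overlapping,
                       file.path(out_dir, "run1_overlapping.tsv"))
    write_unique_table(part$run1$non_overlapping,
                       file.path(out_dir, "run1_non_overlapping.tsv"))
    write_unique_table(part$run2$overlapping,
                       file.path(out_dir, "run2_overlapping.tsv"))
    write_unique_table(part$run2$non_overlapping,
                       file.path(out_dir, "run2_non_overlapping.tsv"))
    write_run2run_stats(stats, file.path(out_dir, "run2run_stats.tsv"))
  }
  stats
}

run_output_block <- function(clean, dd, part) {
  list(n_raw = clean$n_raw,
       n_cleaned = clean$n_cleaned,
       n_unique_identical_only = dd$n_distinct,
       n_unique_full = dd$n_unique,
       n_total_overlap = part$n_total_overlap,
       n_unique_overlap = part$n_unique_overlap)
}

#' Derived run-to-run statistics
#'
#' Completes the derived block of the run-to-run ledger from the output
#' block: redundant cleaned reads and redundancy rate per run, the
#' non-overlapping stratum (totals, uniques, redundant, rate), the
#' overlapping stratum (redundant, rate), and the overlapping-to-cleaned
#' ratios per run and pooled over both runs. All rates follow the
#' redundant-over-unique convention and are reported to one decimal.
#'
#' @param out List with `run1`, `run2` (each holding `n_raw`, `n_cleaned`,
#'   `n_unique_full`, `n_total_overlap`, `n_unique_overlap`) and
#'   `n_unique_overlap_both`.
#' @return The input with per-run derived fields added and
#'   `overlap_over_cleaned_both_pct`.
#' @export
run2run_derived <- function(out) {
  for (run in c("run1", "run2")) {
    b <- out[[run]]
    b$n_redundant_cleaned <- b$n_cleaned - b$n_unique_full
    b$redundancy_rate_pct <- redundancy_rate(b$n_redundant_cleaned,
                                             b$n_unique_full)
    b$n_total_nonoverlap <- b$n_cleaned - b$n_total_overlap
    b$n_unique_nonoverlap <- b$n_unique_full - b$n_unique_overlap
    b$n_redundant_nonoverlap <- b$n_total_nonoverlap - b$n_unique_nonoverlap
    b$n_redundant_overlap <- b$n_total_overlap - b$n_unique_overlap
    derived <- c(b$n_redundant_cleaned, b$n_total_nonoverlap,
                 b$n_unique_nonoverlap, b$n_redundant_nonoverlap,
                 b$n_redundant_overlap)
    if (any(derived < 0))
      stop_seqrunqc(paste0("negative derived count in ", run,
                           ": inconsistent output block"),
                    "consistency_error")
    b$nonoverlap_redundancy_pct <-
      if (b$n_unique_nonoverlap > 0)
        redundancy_rate(b$n_redundant_nonoverlap, b$n_unique_nonoverlap)
      else 0
    b$overlap_redundancy_pct <-
      if (b$n_unique_overlap > 0)
        redundancy_rate(b$n_redundant_overlap, b$n_unique_overlap)
      else 0
    b$overlap_over_cleaned_pct <-
      round(100 * b$n_total_overlap / b$n_cleaned, 1)
    out[[run]] <- b
  }
  out$overlap_over_cleaned_both_pct <- round(
    100 * (out$run1$n_total_overlap + out$run2$n_total_overlap) /
      (out$run1$n_cleaned + out$run2$n_cleaned), 1)
  out
}

run2run_row_labels <- c(
  n_raw = "Total number of raw reads in the run",
  n_cleaned = "Total number of cleaned reads in the run",
  n_unique_identical_only =
    "Number of unique reads in the run (after removing identical redundant reads)",
  n_unique_full =
    "Number of unique reads in the run (after removing identical & inclusive redundant reads)",
  n_total_overlap = "Total number of overlapping reads in the run",
  n_unique_overlap = "Number of unique overlapping reads in the run",
  n_redundant_cleaned = "Number of redundant cleaned reads in the run",
  redundancy_rate_pct = "Redundancy rate within the run",
  n_total_nonoverlap = "Total number of non-overlapping reads in the run",
  n_unique_nonoverlap = "Number of unique non-overlapping reads in the run",
  n_redundant_nonoverlap = "Number of redundant non-overlapping reads in the run",
  nonoverlap_redundancy_pct = "Redundancy of non-overlapping reads in the run",
  n_redundant_overlap = "Number of redundant overlapping reads in the run",
  overlap_redundancy_pct = "Redundancy of overlapping reads in the run",
  overlap_over_cleaned_pct =
    "Total overlapping reads/total cleaned reads (each run)")

write_run2run_stats <- function(stats, path) {
  fmt <- function(key, b) {
    v <- b[[key]]
    if (grepl("_pct$", key)) paste0(formatC(v, format = "f", digits = 1), "%")
    else format(v, big.mark = ",", scientific = FALSE)
  }
  rows <- vapply(names(run2run_row_labels), function(key)
    paste(run2run_row_labels[[key]], fmt(key, stats$run1), fmt(key, stats$run2),
          sep = "\t"), character(1))
  rows <- c("statistic\tRun1\tRun2", unname(rows),
            paste0("Number of unique overlapping reads from both runs\t",
                   stats$n_unique_overlap_both, "\t"),
            paste0("Total overlapping reads/total cleaned reads (both runs)\t",
                   formatC(stats$overlap_over_cleaned_both_pct,
                           format = "f", digits = 1), "%\t"))
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.run2run_stats <- function(x, ...) {
  for (key in names(run2run_row_labels)) {
    cat(run2run_row_labels[[key]], ": ",
        format(x$run1[[key]], big.mark = ","), " / ",
        format(x$run2[[key]], big.mark = ","), "\n", sep = "")
  }
  cat("Number of unique overlapping reads from both runs: ",
      format(x$n_unique_overlap_both, big.mark = ","), "\n", sep = "")
  cat("Total overlapping reads/total cleaned reads (both runs): ",
      x$overlap_over_cleaned_both_pct, "%\n", sep = "")
  invisible(x)
}
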