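#' Collapse identical reads
#'
#' Two reads are identical when they match 100% and have equal length; each
#' distinct base string is keyed once with its multiplicity. With
#' `strand = "both"`, a read and its reverse complement are treated as the
#' same sequence (the lexicographically smaller of the pair is the key).
#'
#' @param bases Character vector of read sequences.
#' @param strand `"forward"` or `"both"`.
#' @return Named integer vector: sequence -> copy count.
#' @export
collapse_identical <- function(bases, strand = "forward") {
  if (length(bases) == 0) return(structure(integer(0), names = character(0)))
  if (strand == "both")
    bases <- pmin(bases, revcomp(bases))
  tab <- table(bases)
  structure(as.integer(tab), names = names(tab))
}

# Is `needle` contained in any of `haystacks` (as an exact substring)?
# Under strand = "both" the reverse complement of the needle also counts.
contained_in <- function(needle, haystacks, strand = "forward") {
  hits <- stringi::stri_detect_fixed(haystacks, needle)
  if (strand == "both")
    hits <- hits | stringi::stri_detect_fixed(haystacks, revcomp(needle))
  hits
}

#' Remove inclusive reads
#'
#' Given distinct sequences with copy counts, removes every sequence that is
#' a proper substring of another surviving (longer) sequence; only the
#' longest read is kept as the unique read. Each removed sequence's count is
#' credited to its longest surviving container (ties broken by
#' lexicographically smallest container). The result is substring-free.
#'
#' @param counts Named integer vector from [collapse_identical()].
#' @param strand `"forward"` or `"both"`.
#' @return An object of class `dedup_result`: list with `uniques` (data frame
#'   `sequence`, `length`, `count`), `n_input`, `n_identical_removed`,
#'   `n_inclusive_removed`, `n_unique`, `redundancy_rate_pct`.
#' @export
remove_inclusive <- function(counts, strand = "forward") {
  seqs <- names(counts)
  n_input <- sum(counts)
  if (length(seqs) == 0) {
    uniques <- data.frame(sequence = character(0), length = integer(0),
                          count = integer(0), stringsAsFactors = FALSE)
    return(new_dedup_result(uniques, 0L, 0L, 0L, 0L))
  }
  # Longest first (ties lexicographic) so every possible container of a
  # sequence is already in the survivor pool when the sequence is examined.
  lens <- nchar(seqs)
  ord <- order(-lens, seqs, method = "radix")
  seqs <- seqs[ord]; lens <- lens[ord]; cts <- as.integer(counts[ord])
  survivors <- character(0)
  surv_count <- integer(0)
  n_inclusive_removed <- 0L
  for (i in seq_along(seqs)) {
    hit <- which(contained_in(seqs[i], survivors, strand))
    if (length(hit) == 0) {
      survivors <- c(survivors, seqs[i])
      surv_count <- c(surv_count, cts[i])
    } else {
      # survivors are in (length desc, lex asc) order, so the first hit is
      # the longest container, ties already lexicographically smallest
      surv_count[hit[1]] <- surv_count[hit[1]] + cts[i]
      n_inclusive_removed <- n_inclusive_removed + cts[i]
    }
  }
  uniques <- data.frame(sequence = survivors, length = nchar(survivors),
                        count = surv_count, stringsAsFactors = FALSE)
  # A removed key's copies all count as inclusive; what remains of the
  # survivors' multiplicities beyond one read each was identical redundancy.
  n_identical_removed <- n_input - n_inclusive_removed - length(survivors)
  new_dedup_result(uniques, n_input, n_identical_removed, n_inclusive_removed,
                   length(seqs))
}

new_dedup_result <- function(uniques, n_input, n_identical, n_inclusive,
                             n_distinct) {
  n_unique <- nrow(uniques)
  rate <- if (n_unique > 0)
    redundancy_rate(n_identical + n_inclusive, n_unique) else NA_real_
  structure(
    list(uniques = uniques, n_input = n_input,
         n_identical_removed = n_identical,
         n_inclusive_removed = n_inclusive,
         n_distinct = n_distinct,
         n_unique = n_unique, redundancy_rate_pct = rate),
    class = "dedup_result")
}

#' Redundancy rate
#'
#' The number of redundant reads expressed as a percentage of the number of
#' unique cleaned reads. Because the denominator is the unique count rather
#' than the total, the rate can exceed 100%.
#'
#' @param n_redundant Number of redundant (identical + inclusive) reads.
#' @param n_unique Number of unique reads (must be >= 1).
#' @return Percentage, rounded to one decimal.
#' @export
redundancy_rate <- function(n_redundant, n_unique) {
  if (any(n_unique == 0))
    stop_seqrunqc("redundancy rate undefined for zero unique reads",
                  "undefined_rate_error")
  round(100 * n_redundant / n_unique, 1)
}

#' Deduplicate a cleaned read set
#'
#' Composes identical-read collapsing and inclusive-read removal.
#'
#' @param bases Character vector of cleaned read sequences.
#' @param strand `"forward"` or `"both"`.
#' @return A `dedup_result`.
#' @export
dedup <- function(bases, strand = "forward") {
  remove_inclusive(collapse_identical(bases, strand), strand)
}

#' Run-level statistics (single-run workflow)
#'
#' Computes the basic statistics of one sequencing run: numbers of raw,
#' cleaned, redundant and unique reads and the redundancy rate, and writes
#' the unique-sequence table.
#'
#' @param clean A `clean_read_set` from [preprocess_run()].
#' @param unique_table_path Where to write the unique-sequence table, or
#'   `NULL` to skip writing.
#' @param strand `"forward"` or `"both"`.
#' @return An object of class `run_stats_result`: the `dedup_result` fields
#'   plus `n_raw` and `n_cleaned`.
#' @export
run_stats <- function(clean, unique_table_path = NULL, strand = "forward") {
  dr <- dedup(clean$reads$bases, strand)
  if (!is.null(unique_table_path))
    write_unique_table(dr$uniques, unique_table_path)
  structure(
    c(list(n_raw = clean$n_raw, n_cleaned = clean$n_cleaned), unclass(dr)),
    class = c("run_stats_result", "dedup_result"))
}

#' @export
print.dedup_result <- function(x, ...) {
  if (!is.null(x$n_raw)) {
    cat("Total number of raw reads:", format(x$n_raw, big.mark = ","), "\n")
    cat("Total number of cleaned reads:", format(x$n_cleaned, big.mark = ","), "\n")
  }
  cat("Number of redundant reads (identical):",
      format(x$n_identical_removed, big.mark = ","), "\n")
  cat("Number of redundant reads (inclusive):",
      format(x$n_inclusive_removed, big.mark = ","), "\n")
  cat("Number of unique reads:", format(x$n_unique, big.mark = ","), "\n")
  cat("Redundancy rate: ", x$redundancy_rate_pct, "%\n", sep = "")
  invisible(x)
}
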