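#' Quality-trim both read ends
#'
#' Removes bases from the 5' and 3' ends while the terminal base quality is
#' below `q_cutoff`; interior low-quality bases are untouched. The result may
#' be empty.
#'
#' @param bases Read sequence (character scalar).
#' @param quals Integer Phred scores, one per base.
#' @param q_cutoff Quality cutoff (default 20).
#' @return List with trimmed `bases` and `quals`.
#' @export
trim_quality_ends <- function(bases, quals, q_cutoff = 20L) {
  keep <- which(quals >= q_cutoff)
  if (length(keep) == 0)
    return(list(bases = "", quals = integer(0)))
  i <- keep[1]; j <- keep[length(keep)]
  list(bases = substr(bases, i, j), quals = quals[i:j])
}

# All adapter placements on a read under the 3'-trimming rule: either the
# whole adapter matches internally, or an adapter prefix of length >=
# min_overlap overlaps the read's 3' terminus; mismatch fraction within the
# matched segment must not exceed max_error_rate. The best placement (longest
# matched segment, ties to the leftmost start) is trimmed together with
# everything 3' of it.
adapter_match_start <- function(bases, adapter, min_overlap, max_error_rate) {
  n <- nchar(bases); m <- nchar(adapter)
  if (n == 0 || m == 0) return(NA_integer_)
  best_len <- 0L; best_start <- NA_integer_
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (start in seq_len(n)) {
    len <- min(m, n - start + 1L)
    full_internal <- len == m
    terminal <- (start + len - 1L) == n
    if (!full_internal && !(terminal && len >= min_overlap)) next
    mism <- sum(b[start:(start + len - 1L)] != a[seq_len(len)])
    if (mism / len > max_error_rate) next
    if (len > best_len) { best_len <- len; best_start <- start }
  }
  best_start
}

#' Trim an adapter from a read 3' end
#'
#' Finds the best match of the adapter in the read — a full internal match,
#' or an adapter prefix overlapping the read's 3' terminus by at least
#' `min_overlap` bases — with mismatch fraction at most `max_error_rate`, and
#' removes it together with everything 3' of it. With no adapter configured
#' the read is returned unchanged.
#'
#' @param bases Read sequence.
#' @param quals Integer Phred scores.
#' @param adapter Adapter sequence or `NULL`.
#' @param min_overlap Minimum terminal overlap (default 3).
#' @param max_error_rate Maximum mismatch fraction (default 0.1).
#' @return List with trimmed `bases` and `quals`.
#' @export
trim_adapter <- function(bases, quals, adapter = NULL, min_overlap = 3L,
                         max_error_rate = 0.1) {
  if (is.null(adapter))
    return(list(bases = bases, quals = quals))
  start <- adapter_match_start(bases, adapter, min_overlap, max_error_rate)
  if (is.na(start))
    return(list(bases = bases, quals = quals))
  list(bases = substr(bases, 1L, start - 1L),
       quals = quals[seq_len(start - 1L)])
}

#' Remove reads containing N
#'
#' @param reads A `read_set` data frame.
#' @return List with `reads` (N-free subset, order preserved) and `n_removed`.
#' @export
drop_n_reads <- function(reads) {
  has_n <- stringi::stri_detect_fixed(reads$bases, "N")
  list(reads = read_set(reads$read_id[!has_n], reads$bases[!has_n],
                        reads$quals[!has_n]),
       n_removed = sum(has_n))
}

#' Preprocess a sequencing run
#'
#' Cleans raw reads with the per-read pipeline: adapter trim, quality-end
#' trim at the configured cutoff, removal of N-containing reads, removal of
#' reads shorter than the minimum length. Raw/cleaned/dropped counters are
#' maintained and conserved (`n_raw == n_cleaned + n_dropped_n +
#' n_dropped_short`).
#'
#' @param x Path to a FASTQ file, or a `read_set` data frame of raw reads.
#' @param config A [run_config()].
#' @return An object of class `clean_read_set`: list with `reads`
#'   (`read_set`), `n_raw`, `n_cleaned`, `n_dropped_n`, `n_dropped_short`.
#' @export
preprocess_run <- function(x, config = run_config()) {
  reads <- if (is.character(x)) read_fastq(x, config$phred_offset) else x
  n_raw <- n_reads(reads)
  bases <- reads$bases
  quals <- reads$quals
  for (i in seq_len(n_raw)) {
    r <- trim_adapter(bases[i], quals[[i]], config$adapter,
                      config$adapter_min_overlap, config$adapter_max_error_rate)
    r <- trim_quality_ends(r$bases, r$quals, config$q_cutoff)
    bases[i] <- r$bases
    quals[[i]] <- r$quals
  }
  has_n <- stringi::stri_detect_fixed(bases, "N")
  too_short <- !has_n & nchar(bases) < max(1L, config$min_length)
  keep <- !has_n & !too_short
  structure(
    list(reads = read_set(reads$read_id[keep], bases[keep], quals[keep]),
         n_raw = n_raw,
         n_cleaned = sum(keep),
         n_dropped_n = sum(has_n),
         n_dropped_short = sum(too_short)),
    class = "clean_read_set")
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat("Cleaned read set\n")
  cat("  raw reads:      ", x$n_raw, "\n")
  cat("  cleaned reads:  ", x$n_cleaned, "\n")
  cat("  dropped (N):    ", x$n_dropped_n, "\n")
  cat("  dropped (short):", x$n_dropped_short, "\n")
  invisible(x)
}
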