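CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

# Parse a CIGAR string into a data frame of (len, op) pairs.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    stop_seqrunqc(paste0("unparseable CIGAR: ", cigar), "cigar_parse_error")
  toks <- stringi::stri_match_all_regex(cigar, "([0-9]+)([A-Za-z=])")[[1]]
  if (anyNA(toks) ||
      paste0(toks[, 1], collapse = "") != cigar ||
      !all(toks[, 3] %in% CIGAR_OPS))
    stop_seqrunqc(paste0("unparseable CIGAR: ", cigar), "cigar_parse_error")
  data.frame(len = as.integer(toks[, 2]), op = toks[, 3],
             stringsAsFactors = FALSE)
}

#' Reference intervals covered by an alignment
#'
#' Walks a CIGAR string from a 1-based leftmost mapping position and returns
#' the reference intervals the alignment covers. M, `=` and X operations
#' cover reference bases; D and N advance the reference cursor without
#' covering; I, S, H and P consume no reference at all.
#'
#' @param pos 1-based leftmost mapping position.
#' @param cigar CIGAR string.
#' @return List with `intervals` (two-column matrix of 0-based half-open
#'   `[start, end)` reference intervals) and `span` (total reference bases
#'   consumed, covered or not).
#' @export
cigar_reference_intervals <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  cursor <- pos - 1L  # 0-based
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      starts <- c(starts, cursor); ends <- c(ends, cursor + len)
      cursor <- cursor + len
    } else if (op %in% c("D", "N")) {
      cursor <- cursor + len
    }
    # I, S, H, P: no reference consumed
  }
  list(intervals = cbind(start = starts, end = ends),
       span = cursor - (pos - 1L))
}

#' Accumulate per-base coverage depth
#'
#' Adds each usable alignment's covered reference intervals into per-scaffold
#' depth arrays. Records flagged unmapped (0x4), secondary (0x100) or
#' supplementary (0x800) are excluded, so each mapped read is counted once at
#' its primary locus.
#'
#' @param alignments Alignment data frame from [parse_sam()] or
#'   [exact_match_align()].
#' @param scaffolds Scaffold table (`name`, `length`).
#' @return List with `depths` (named list of integer vectors) and
#'   `n_reads_mapped` (number of records accumulated).
#' @export
accumulate_depth <- function(alignments, scaffolds) {
  # difference-array accumulation: +1 at interval starts, -1 at ends, cumsum
  delta <- lapply(structure(scaffolds$length, names = scaffolds$name),
                  function(L) integer(L + 1L))
  skip_mask <- bitwOr(bitwOr(4L, 256L), 2048L)
  usable <- if ("usable" %in% names(alignments)) alignments$usable
            else rep(TRUE, nrow(alignments))
  include <- usable & bitwAnd(alignments$flag, skip_mask) == 0L
  n_mapped <- 0L
  for (i in which(include)) {
    rname <- alignments$rname[i]
    if (is.null(delta[[rname]]))
      stop_seqrunqc(paste0("alignment ", i, " references unknown scaffold ",
                           rname), "sam_unknown_reference_error")
    civ <- cigar_reference_intervals(alignments$pos[i], alignments$cigar[i])
    iv <- civ$intervals
    L <- length(delta[[rname]]) - 1L
    if (nrow(iv) && max(iv[, "end"]) > L)
      stop_seqrunqc(
        paste0("alignment ", i, " extends past the end of scaffold ", rname,
               " (position ", max(iv[, "end"]), " > length ", L, ")"),
        "coverage_out_of_bounds_error")
    for (k in seq_len(nrow(iv))) {
      delta[[rname]][iv[k, "start"] + 1L] <-
        delta[[rname]][iv[k, "start"] + 1L] + 1L
      delta[[rname]][iv[k, "end"] + 1L] <-
        delta[[rname]][iv[k, "end"] + 1L] - 1L
    }
    n_mapped <- n_mapped + 1L
  }
  depths <- lapply(delta, function(d) cumsum(d[-length(d)]))
  list(depths = depths, n_reads_mapped = n_mapped)
}

#' Summarize genome coverage
#'
#' Per-scaffold and genome-wide coverage statistics: breadth (percentage of
#' reference bases covered by at least one read), depth (mean times each
#' reference base is covered) and evenness (the coefficient of variation —
#' population SD over mean — of per-scaffold coverage breadth, computed over
#' all scaffolds including uncovered ones).
#'
#' @param depths Named list of per-scaffold integer depth vectors.
#' @param scaffolds Scaffold table (`name`, `length`).
#' @param n_cleaned Number of cleaned reads that entered alignment (for the
#'   mapped/cleaned ratio), or `NA`.
#' @param n_reads_mapped Number of reads accumulated into the depths, or `NA`.
#' @return List with `summary` (class `coverage_summary`) and `per_scaffold`
#'   (data frame: `name`, `length`, `covered_bases`, `mapped_bases`,
#'   `breadth_pct`, `depth_mean`).
#' @export
summarize_coverage <- function(depths, scaffolds, n_cleaned = NA_integer_,
                               n_reads_mapped = NA_integer_) {
  if (nrow(scaffolds) == 0 || sum(scaffolds$length) == 0)
    stop_seqrunqc("cannot summarize coverage of a zero-length genome",
                  "coverage_error")
  covered <- vapply(scaffolds$name, function(nm) sum(depths[[nm]] > 0), 0L)
  mapped <- vapply(scaffolds$name,
                   function(nm) sum(as.numeric(depths[[nm]])), 0)
  per_scaffold <- data.frame(
    name = scaffolds$name, length = scaffolds$length,
    covered_bases = as.integer(covered), mapped_bases = mapped,
    breadth_pct = 100 * covered / scaffolds$length,
    depth_mean = mapped / scaffolds$length,
    stringsAsFactors = FALSE, row.names = NULL)
  breadth_mean <- mean(per_scaffold$breadth_pct)
  breadth_sd <- pop_sd(per_scaffold$breadth_pct)
  depth_mean <- mean(per_scaffold$depth_mean)
  depth_sd <- pop_sd(per_scaffold$depth_mean)
  n_cov <- sum(covered >= 1)
  summary <- structure(list(
    n_scaffolds_total = nrow(scaffolds),
    n_scaffolds_covered = n_cov,
    covered_scaffold_pct = 100 * n_cov / nrow(scaffolds),
    genome_breadth_pct = 100 * sum(covered) / sum(scaffolds$length),
    genome_depth = sum(mapped) / sum(scaffolds$length),
    evenness = if (breadth_mean > 0) breadth_sd / breadth_mean else NA_real_,
    breadth_mean = breadth_mean, breadth_sd = breadth_sd,
    depth_mean = depth_mean, depth_sd = depth_sd,
    n_reads_mapped = n_reads_mapped,
    mapped_over_cleaned_pct =
      if (is.na(n_cleaned) || is.na(n_reads_mapped)) NA_real_
      else 100 * n_reads_mapped / n_cleaned),
    class = "coverage_summary")
  list(summary = summary, per_scaffold = per_scaffold)
}

#' Histogram scaffolds by coverage breadth and depth
#'
#' Bins are open at the lower end and closed at the higher end, with a
#' dedicated bin for uncovered scaffolds: breadth bins are \{0\},
#' (0,10], (10,20], ..., (90,100] percent; depth bins are \{0\} plus
#' intervals between the configured edges and an open-ended top bin.
#'
#' @param per_scaffold Per-scaffold table from [summarize_coverage()].
#' @param depth_edges Upper edges of the finite depth bins.
#' @return List of two data frames (`breadth`, `depth`) with columns `bin`
#'   and `n_scaffolds`; counts in each sum to the number of scaffolds.
#' @export
bin_distributions <- function(per_scaffold, depth_edges = c(1, 2, 4, 10)) {
  b <- per_scaffold$breadth_pct
  b_edges <- seq(0, 100, by = 10)
  b_labels <- c("0", sprintf("(%d,%d]", b_edges[-11], b_edges[-1]))
  b_bin <- ifelse(b == 0, 1L, 1L + findInterval(b, b_edges, left.open = TRUE))
  breadth <- data.frame(
    bin = b_labels,
    n_scaffolds = tabulate(b_bin, nbins = length(b_labels)),
    stringsAsFactors = FALSE)

  d <- per_scaffold$depth_mean
  lower <- c(0, depth_edges)
  d_labels <- c("0",
                sprintf("(%g,%g]", lower[-length(lower)], depth_edges),
                sprintf("(%g,Inf)", depth_edges[length(depth_edges)]))
  d_bin <- ifelse(d == 0, 1L,
                  1L + findInterval(d, c(0, depth_edges), left.open = TRUE))
  depth <- data.frame(
    bin = d_labels,
    n_scaffolds = tabulate(d_bin, nbins = length(d_labels)),
    stringsAsFactors = FALSE)
  list(breadth = breadth, depth = depth)
}

#' @export
print.coverage_summary <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  if (!is.na(x$n_reads_mapped))
    cat("Total number of reads mapped to reference genome:",
        format(x$n_reads_mapped, big.mark = ","), "\n")
  if (!is.na(x$mapped_over_cleaned_pct))
    cat("Mapped/Cleaned reads (%):", fmt(x$mapped_over_cleaned_pct), "\n")
  cat("Total number of scaffolds in reference genome:",
      x$n_scaffolds_total, "\n")
  cat("Number of covered reference scaffolds:", x$n_scaffolds_covered, "\n")
  cat("Covered/Total scaffolds (%):", fmt(x$covered_scaffold_pct), "\n")
  cat("Genome coverage breadth (%):", fmt(x$genome_breadth_pct), "\n")
  cat("Genome coverage depth:", fmt(x$genome_depth), "\n")
  cat("Standard deviation of scaffold coverage depth:", fmt(x$depth_sd), "\n")
  cat("Average scaffold coverage depth:", fmt(x$depth_mean), "\n")
  cat("Genome coverage evenness:", fmt(x$evenness), "\n")
  invisible(x)
}
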