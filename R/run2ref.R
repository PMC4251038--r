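#' Exact-match internal aligner
#'
#' Reports every exact full-length forward-strand occurrence of each read in
#' the reference, as an ungapped `<len>M` alignment. The first occurrence
#' (reference order, then position) is primary; further occurrences carry the
#' secondary flag (0x100); reads with no occurrence are emitted with the
#' unmapped flag (0x4). Intended for validation and alignment-free testing —
#' real analyses should supply a SAM file from a production aligner.
#'
#' @param reads A `read_set` data frame (or character vector of sequences).
#' @param scaffolds Scaffold table with `sequence` present.
#' @return Alignment data frame (`qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `usable`) compatible with [accumulate_depth()].
#' @export
exact_match_align <- function(reads, scaffolds) {
  bases <- if (is.character(reads)) reads else reads$bases
  ids <- if (is.character(reads)) paste0("r", seq_along(reads))
         else reads$read_id
  if (any(is.na(scaffolds$sequence)))
    stop_seqrunqc("reference sequences are required for internal alignment",
                  "alignment_error")
  rows <- vector("list", length(bases))
  for (i in seq_along(bases)) {
    hits_rname <- character(0); hits_pos <- integer(0)
    for (j in seq_len(nrow(scaffolds))) {
      occ <- stringi::stri_locate_all_fixed(
        scaffolds$sequence[j], bases[i], overlap = TRUE)[[1]]
      if (!anyNA(occ[, 1])) {
        hits_rname <- c(hits_rname, rep(scaffolds$name[j], nrow(occ)))
        hits_pos <- c(hits_pos, occ[, 1])
      }
    }
    if (length(hits_pos) == 0) {
      rows[[i]] <- data.frame(qname = ids[i], flag = 4L, rname = "*",
                              pos = 0L, cigar = "*", usable = FALSE,
                              stringsAsFactors = FALSE)
    } else {
      flags <- c(0L, rep(256L, length(hits_pos) - 1L))
      rows[[i]] <- data.frame(qname = ids[i], flag = flags,
                              rname = hits_rname, pos = hits_pos,
                              cigar = paste0(nchar(bases[i]), "M"),
                              usable = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run-to-reference coverage workflow
#'
#' Computes genome-wide coverage breadth, depth and evenness of a read set at
#' nucleotide resolution. Alignments come either from a SAM file produced by
#' any external aligner, or from the internal exact-match aligner applied to
#' cleaned reads and a reference with sequences.
#'
#' @param clean A `clean_read_set` (required unless `sam` is given; used for
#'   the mapped/cleaned ratio and internal alignment).
#' @param reference Scaffold table from [read_fasta()]; optional when `sam`
#'   carries `@SQ` lengths.
#' @param sam Path to a SAM file, or `NULL` to use the internal aligner.
#' @param out_dir Directory for output files (`per_scaffold.tsv`,
#'   `coverage_summary.tsv`, `depth_track.tsv`, `breadth_histogram.tsv`,
#'   `depth_histogram.tsv`), or `NULL` to skip writing.
#' @param config A [run_config()].
#' @return List of class `run2ref_result`: `summary` (`coverage_summary`),
#'   `per_scaffold`, `histograms`, `depths`, `n_reads_mapped`.
#' @export
run2ref <- function(clean = NULL, reference = NULL, sam = NULL,
                    out_dir = NULL, config = run_config()) {
  if (!is.null(sam)) {
    parsed <- parse_sam(sam)
    scaffolds <- if (!is.null(reference)) reference else parsed$scaffolds
    alignments <- parsed$alignments
  } else {
    if (is.null(clean) || is.null(reference))
      stop_seqrunqc("either a SAM path or cleaned reads plus a reference are required",
                    "usage_error")
    scaffolds <- reference
    alignments <- exact_match_align(clean$reads, reference)
  }
  acc <- accumulate_depth(alignments, scaffolds)
  n_cleaned <- if (!is.null(clean)) clean$n_cleaned else NA_integer_
  cov <- summarize_coverage(acc$depths, scaffolds, n_cleaned,
                            acc$n_reads_mapped)
  hist <- bin_distributions(cov$per_scaffold, config$depth_bin_edges)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ps <- cov$per_scaffold
    ps$breadth_pct <- round(ps$breadth_pct, 2)
    ps$depth_mean <- round(ps$depth_mean, 2)
    write.table(ps, file.path(out_dir, "per_scaffold.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_coverage_summary(cov$summary, file.path(out_dir, "coverage_summary.tsv"))
    write_depth_track(acc$depths, scaffolds,
                      file.path(out_dir, "depth_track.tsv"),
                      emit_zeros = config$emit_zeros)
    write.table(hist$breadth, file.path(out_dir, "breadth_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hist$depth, file.path(out_dir, "depth_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(summary = cov$summary, per_scaffold = cov$per_scaffold,
                 histograms = hist, depths = acc$depths,
                 n_reads_mapped = acc$n_reads_mapped),
            class = "run2ref_result")
}

write_coverage_summary <- function(s, path) {
  r2 <- function(v) formatC(v, format = "f", digits = 2)
  rows <- c(
    "Total number of reads mapped to reference genome" =
      as.character(s$n_reads_mapped),
    "Mapped/Cleaned reads (%)" = r2(s$mapped_over_cleaned_pct),
    "Total number of scaffolds in reference genome" =
      as.character(s$n_scaffolds_total),
    "Number of covered reference scaffolds" =
      as.character(s$n_scaffolds_covered),
    "Covered/Total scaffolds (%)" = r2(s$covered_scaffold_pct),
    "Genome coverage breadth (%)" = r2(s$genome_breadth_pct),
    "Genome coverage depth" = r2(s$genome_depth),
    "Standard deviation of scaffold coverage breadth" = r2(s$breadth_sd),
    "Average scaffold coverage breadth" = r2(s$breadth_mean),
    "Standard deviation of scaffold coverage depth" = r2(s$depth_sd),
    "Average scaffold coverage depth" = r2(s$depth_mean),
    "Genome coverage evenness" = r2(s$evenness))
  writeLines(paste(names(rows), rows, sep = "\t"), path)
  invisible(path)
}
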