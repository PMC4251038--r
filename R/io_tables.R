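#' Write a unique-sequence table
#'
#' Writes collapsed unique sequences as a tab-delimited file with columns
#' `sequence_id`, `length`, `count`, `sequence`. Rows are sorted by
#' descending count, then descending length, then lexicographic sequence, so
#' output is byte-reproducible.
#'
#' @param uniques Data frame with columns `sequence`, `length`, `count`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_unique_table <- function(uniques, path) {
  ord <- order(-uniques$count, -uniques$length, uniques$sequence,
               method = "radix")
  u <- uniques[ord, , drop = FALSE]
  out <- data.frame(sequence_id = if (nrow(u)) paste0("u", seq_len(nrow(u)))
                    else character(0),
                    length = u$length, count = u$count, sequence = u$sequence,
                    stringsAsFactors = FALSE)
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop_seqrunqc(
      paste0("cannot write unique table to ", path, ": ",
             conditionMessage(e)), "io_error"))
  invisible(path)
}

#' Read a unique-sequence table
#'
#' @param path Path written by [write_unique_table()].
#' @return Data frame with columns `sequence_id`, `length`, `count`,
#'   `sequence`.
#' @export
read_unique_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses =
               c("character", "integer", "integer", "character"))
}

#' Write a per-base coverage depth track
#'
#' Emits a three-column tab-delimited track (`scaffold`, 1-based `pos`,
#' `depth`) at nucleotide resolution, in reference scaffold order — the shape
#' genome browsers and `samtools depth`-style consumers expect. Zero-depth
#' positions are omitted by default to bound file size.
#'
#' @param depths Named list of integer depth vectors, one per scaffold, each
#'   as long as its scaffold.
#' @param scaffolds Scaffold table (`name`, `length`) giving reference order.
#' @param path Output path.
#' @param emit_zeros Include zero-depth positions when `TRUE`.
#' @return The path, invisibly.
#' @export
write_depth_track <- function(depths, scaffolds, path, emit_zeros = FALSE) {
  chunks <- character(0)
  for (i in seq_len(nrow(scaffolds))) {
    nm <- scaffolds$name[i]
    d <- depths[[nm]]
    if (is.null(d) || length(d) != scaffolds$length[i])
      stop_seqrunqc(
        paste0("depth array for scaffold ", nm,
               " does not match its length (", scaffolds$length[i], ")"),
        "depth_consistency_error")
    keep <- if (emit_zeros) seq_along(d) else which(d > 0)
    if (length(keep))
      chunks <- c(chunks, paste(nm, keep, d[keep], sep = "\t"))
  }
  writeLines(chunks, path)
  invisible(path)
}
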