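#' Parse a SAM file (coverage subset)
#'
#' Reads the subset of a SAM file needed for coverage analysis: `@SQ` header
#' lines (scaffold names and lengths) and, from each alignment line, the
#' FLAG, RNAME, POS and CIGAR fields. All other header lines and all optional
#' fields are ignored. Alignment lines whose RNAME or CIGAR is `"*"` are kept
#' but flagged unusable.
#'
#' @param path Path to a SAM text file.
#' @return A list with `scaffolds` (data frame: `name`, `length`; `sequence`
#'   is `NA` since only header lengths are available) and `alignments`
#'   (data frame: `flag`, `rname`, `pos`, `cigar`, `usable`).
#' @export
parse_sam <- function(path) {
  if (!file.exists(path))
    stop_seqrunqc(paste0("no such file: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, "@")
  sq <- lines[is_header & startsWith(lines, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  if (length(sq) && (anyNA(ln) || any(sn == sq)))
    stop_seqrunqc("malformed @SQ header line (missing SN or LN tag)",
                  "sam_format_error")
  scaffolds <- data.frame(name = sn, length = ln, sequence = NA_character_,
                          stringsAsFactors = FALSE)
  aln_lines <- lines[!is_header]
  if (length(aln_lines) == 0) {
    alignments <- data.frame(flag = integer(0), rname = character(0),
                             pos = integer(0), cigar = character(0),
                             usable = logical(0), stringsAsFactors = FALSE)
    return(list(scaffolds = scaffolds, alignments = alignments))
  }
  fields <- stringi::stri_split_fixed(aln_lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop_seqrunqc(
      paste0("malformed alignment line ", which(nf < 6)[1],
             ": fewer than 6 tab-delimited fields"),
      "sam_format_error")
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cigar <- vapply(fields, `[[`, character(1), 6L)
  usable <- rname != "*" & cigar != "*" & !bitwAnd(flag, 4L)
  unknown <- usable & !(rname %in% scaffolds$name)
  if (any(unknown))
    stop_seqrunqc(
      paste0("alignment references scaffold absent from @SQ header: ",
             rname[unknown][1]),
      "sam_unknown_reference_error")
  list(scaffolds = scaffolds,
       alignments = data.frame(flag = flag, rname = rname, pos = pos,
                               cigar = cigar, usable = usable,
                               stringsAsFactors = FALSE))
}

#' Write alignment records as a minimal SAM file
#'
#' Emits an `@SQ` header from the scaffold table and one line per alignment
#' with placeholder fields outside FLAG/RNAME/POS/CIGAR.
#'
#' @param alignments Data frame with `flag`, `rname`, `pos`, `cigar` and
#'   optionally `qname`.
#' @param scaffolds Scaffold table (`name`, `length`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, scaffolds, path) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", scaffolds$name, "\tLN:", scaffolds$length))
  qname <- if ("qname" %in% names(alignments)) alignments$qname else
    paste0("r", seq_len(nrow(alignments)))
  body <- paste(qname, alignments$flag, alignments$rname, alignments$pos,
                255L, alignments$cigar, "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
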