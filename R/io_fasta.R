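#' Read a reference FASTA file
#'
#' Reads a (multi-scaffold) FASTA file into a scaffold table. Scaffold names
#' are the header token up to the first whitespace; sequences are uppercased
#' and file order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `name`, `length`, and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop_seqrunqc(paste0("no such file: ", path), "io_error")
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_seqrunqc(
      paste0("FASTA format error in ", path, ": ", conditionMessage(e)),
      "fasta_format_error"))
  nm <- sub("[ \t].*$", "", names(set))
  seqs <- toupper(as.character(set))
  widths <- nchar(seqs)
  if (any(widths == 0))
    stop_seqrunqc(
      paste0("zero-length scaffold in ", path, ": ", nm[widths == 0][1]),
      "fasta_format_error")
  if (anyDuplicated(nm))
    stop_seqrunqc(
      paste0("duplicate scaffold name in ", path, ": ",
             nm[duplicated(nm)][1]),
      "fasta_format_error")
  data.frame(name = nm, length = widths, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a scaffold table as FASTA
#'
#' @param scaffolds Data frame with `name` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return The path, invisibly.
#' @export
write_fasta <- function(scaffolds, path, width = 70L) {
  out <- character(0)
  for (i in seq_len(nrow(scaffolds))) {
    s <- scaffolds$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", scaffolds$name[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}
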