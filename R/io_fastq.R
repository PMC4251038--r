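#' Read a FASTQ file
#'
#' Reads a four-line-per-record FASTQ file (plain or gzip-compressed) into a
#' read-set data frame with decoded per-base Phred qualities.
#'
#' @param path Path to a FASTQ file.
#' @param phred_offset ASCII offset of the quality encoding (default 33).
#' @return A `read_set` data frame with columns `read_id`, `bases` (uppercase
#'   DNA), and `quals` (list column of integer Phred scores).
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path))
    stop_seqrunqc(paste0("no such file: ", path), "io_error")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(read_set())
  if (length(lines) %% 4L != 0L)
    stop_seqrunqc(
      paste0("truncated FASTQ record at end of ", path,
             " (line count not a multiple of 4)"),
      "fastq_truncation_error")
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  bases <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  if (any(!startsWith(headers, "@")))
    stop_seqrunqc(
      paste0("malformed FASTQ record ", which(!startsWith(headers, "@"))[1],
             ": header does not start with '@'"),
      "fastq_malformed_error")
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad))
    stop_seqrunqc(
      paste0("malformed FASTQ record ", bad[1],
             ": sequence and quality lengths differ (",
             nchar(bases[bad[1]]), " vs ", nchar(quals[bad[1]]), ")"),
      "fastq_malformed_error")
  ids <- sub("^@", "", headers)
  ids <- sub("[ \t].*$", "", ids)
  read_set(ids, bases, lapply(quals, decode_quals, phred_offset = phred_offset))
}

#' Write a read set as FASTQ
#'
#' @param reads A `read_set` data frame.
#' @param path Output path (written plain, not compressed).
#' @param phred_offset ASCII offset used to encode qualities.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path, phred_offset = 33L) {
  n <- n_reads(reads)
  if (n == 0) {
    file.create(path)
    return(invisible(path))
  }
  qual_strings <- vapply(reads$quals, encode_quals, character(1),
                         phred_offset = phred_offset)
  rec <- character(4L * n)
  rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
  rec[seq(2L, by = 4L, length.out = n)] <- reads$bases
  rec[seq(3L, by = 4L, length.out = n)] <- "+"
  rec[seq(4L, by = 4L, length.out = n)] <- qual_strings
  writeLines(rec, path)
  invisible(path)
}
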