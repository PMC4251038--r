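#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd
#' @importFrom utils write.table read.delim
NULL

# Reverse-complement of uppercase DNA strings (N maps to N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

# Decode an ASCII quality string into integer Phred scores.
decode_quals <- function(qual_string, phred_offset = 33L) {
  if (!nzchar(qual_string)) return(integer(0))
  utf8ToInt(qual_string) - as.integer(phred_offset)
}

encode_quals <- function(quals, phred_offset = 33L) {
  if (length(quals) == 0) return("")
  intToUtf8(as.integer(quals) + as.integer(phred_offset))
}

# Population standard deviation (divide by N), the convention used for
# scaffold-level coverage spread so single-scaffold genomes are well defined.
pop_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Assemble a read-set data frame. `quals` is a list column of integer vectors,
# one per read, always the same length as the base string.
read_set <- function(read_id = character(0), bases = character(0),
                     quals = list()) {
  stopifnot(length(read_id) == length(bases), length(bases) == length(quals))
  structure(
    list(read_id = as.character(read_id), bases = as.character(bases),
         quals = quals),
    class = c("read_set", "data.frame"),
    row.names = seq_along(read_id)
  )
}

n_reads <- function(reads) length(reads$bases)

stop_seqrunqc <- function(msg, class) {
  stop(structure(class = c(class, "seqrunqc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
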