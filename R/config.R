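#' Analysis configuration
#'
#' Builds and validates the configuration shared by all workflows. Unknown
#' keys are rejected so that a typo in a config file or on the command line
#' fails before any work is done.
#'
#' @param adapter Adapter sequence to trim from read 3' ends, or `NULL`
#'   (default) to disable adapter trimming.
#' @param q_cutoff Phred quality cutoff for end trimming (default 20): bases
#'   are removed from both read ends while the terminal base quality is below
#'   this value.
#' @param phred_offset ASCII offset of the FASTQ quality encoding
#'   (default 33, Sanger/Illumina 1.8+).
#' @param min_length Minimum read length after trimming (default 1, i.e. only
#'   reads that trim to nothing are dropped).
#' @param adapter_min_overlap Minimum 3'-terminal overlap between read and
#'   adapter prefix for a trim to be accepted (default 3).
#' @param adapter_max_error_rate Maximum mismatch fraction within the matched
#'   adapter segment (default 0.1).
#' @param strand `"forward"` (default) tests identity/containment on the
#'   forward strand only; `"both"` also tests the reverse complement.
#' @param depth_bin_edges Upper edges of the finite depth-histogram bins; bins
#'   are open below and closed above, with a separate zero bin and a final
#'   open-ended bin above the last edge.
#' @param emit_zeros Whether the per-base depth track includes zero-depth
#'   positions (default `FALSE`).
#' @param seed Integer seed for the synthetic-data generator.
#' @param threads Accepted for interface compatibility; results are
#'   thread-count invariant.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(adapter = NULL,
                       q_cutoff = 20L,
                       phred_offset = 33L,
                       min_length = 1L,
                       adapter_min_overlap = 3L,
                       adapter_max_error_rate = 0.1,
                       strand = c("forward", "both"),
                       depth_bin_edges = c(1, 2, 4, 10),
                       emit_zeros = FALSE,
                       seed = 1L,
                       threads = 1L) {
  strand <- match.arg(strand)
  if (!is.null(adapter)) {
    adapter <- toupper(as.character(adapter))
    if (!nzchar(adapter) || grepl("[^ACGTN]", adapter))
      stop_seqrunqc("adapter must be a non-empty DNA string", "config_error")
  }
  if (q_cutoff < 0) stop_seqrunqc("q_cutoff must be >= 0", "config_error")
  if (min_length < 0) stop_seqrunqc("min_length must be >= 0", "config_error")
  if (adapter_min_overlap < 1)
    stop_seqrunqc("adapter_min_overlap must be >= 1", "config_error")
  if (adapter_max_error_rate < 0 || adapter_max_error_rate > 1)
    stop_seqrunqc("adapter_max_error_rate must be in [0,1]", "config_error")
  if (is.unsorted(depth_bin_edges, strictly = TRUE) || any(depth_bin_edges <= 0))
    stop_seqrunqc("depth_bin_edges must be positive and strictly increasing",
                  "config_error")
  if (threads < 1) stop_seqrunqc("threads must be >= 1", "config_error")
  structure(
    list(adapter = adapter,
         q_cutoff = as.integer(q_cutoff),
         phred_offset = as.integer(phred_offset),
         min_length = as.integer(min_length),
         adapter_min_overlap = as.integer(adapter_min_overlap),
         adapter_max_error_rate = adapter_max_error_rate,
         strand = strand,
         depth_bin_edges = as.numeric(depth_bin_edges),
         emit_zeros = isTRUE(emit_zeros),
         seed = as.integer(seed),
         threads = as.integer(threads)),
    class = "run_config"
  )
}

# Build a run_config from a named list (e.g. parsed YAML/JSON or CLI flags),
# rejecting unknown keys.
config_from_list <- function(x) {
  if (is.null(x)) return(run_config())
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop_seqrunqc(paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")), "config_error")
  do.call(run_config, x)
}
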