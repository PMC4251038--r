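# Small constructors for tests: a unique table from a named count vector and
# a clean_read_set from bare sequences (constant Q40).
mk_uniques <- function(counts) {
  data.frame(sequence = names(counts), length = nchar(names(counts)),
             count = as.integer(counts), stringsAsFactors = FALSE)
}

mk_clean <- function(bases, n_raw = length(bases)) {
  structure(list(
    reads = seqrunqc:::read_set(paste0("r", seq_along(bases)), bases,
                                lapply(nchar(bases), function(L)
                                  rep(40L, L))),
    n_raw = n_raw, n_cleaned = length(bases),
    n_dropped_n = n_raw - length(bases), n_dropped_short = 0L),
    class = "clean_read_set")
}
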