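#' Generate the synthetic validation dataset
#'
#' Builds a small dataset with fully known ground truth, mirroring the kind
#' of construction used to validate read-level toolkits: 10 artificial
#' chromosomes are clipped as disjoint 150-bp fragments from a source genome;
#' from each chromosome, 10 read templates of 75-100 bp are clipped at seeded
#' positions; each template is emitted 10 times at constant quality Q40,
#' giving 1,000 reads. Templates are redrawn until the set of 100 is pairwise
#' substring-free, so the expected truth is exactly 100 unique sequences of
#' copy number 10 (redundancy rate 900%), and the expected covered intervals
#' of each chromosome are the union of its template clip windows.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param source Optional scaffold table (e.g. from [read_fasta()]) to clip
#'   chromosomes from; by default a seeded random 5-kb genome is used so no
#'   external download is ever needed.
#' @param out_dir Directory to write `reference.fasta`, `reads.fastq` and
#'   `truth.json`, or `NULL` to skip writing.
#' @param n_chromosomes,chrom_length,templates_per_chrom,read_length_range,copies
#'   Construction parameters; defaults are the study conditions.
#' @return List of class `synthetic_run`: `reference` (scaffold table),
#'   `reads` (`read_set`), and `truth` (chromosome clip coordinates, template
#'   coordinates and sequences, expected unique/copy counts, expected covered
#'   intervals per scaffold).
#' @export
make_synthetic_run <- function(seed = 1L, source = NULL, out_dir = NULL,
                               n_chromosomes = 10L, chrom_length = 150L,
                               templates_per_chrom = 10L,
                               read_length_range = c(75L, 100L),
                               copies = 10L) {
  set.seed(seed)
  if (is.null(source)) {
    src_seq <- paste(sample(c("A", "C", "G", "T"), 5000L, replace = TRUE),
                     collapse = "")
    src_name <- "synthetic_source"
  } else {
    src_seq <- source$sequence[1]
    src_name <- source$name[1]
  }
  if (nchar(src_seq) < n_chromosomes * chrom_length)
    stop_seqrunqc(
      paste0("source sequence too short: need at least ",
             n_chromosomes * chrom_length, " bases"),
      "synthetic_source_error")
  # disjoint 150-bp windows: sample among non-overlapping blocks
  n_blocks <- nchar(src_seq) %/% chrom_length
  blocks <- sort(sample.int(n_blocks, n_chromosomes))
  chrom_start <- (blocks - 1L) * chrom_length + 1L
  chrom_seq <- substring(src_seq, chrom_start, chrom_start + chrom_length - 1L)
  chrom_name <- sprintf("chr%02d", seq_len(n_chromosomes))
  reference <- data.frame(name = chrom_name, length = chrom_length,
                          sequence = chrom_seq, stringsAsFactors = FALSE)

  templates <- draw_templates(reference, templates_per_chrom,
                              read_length_range)
  # one block of `copies` identical reads per template; an interleaved
  # half-split therefore leaves copies/2 per half for every template
  n_templates <- nrow(templates)
  idx <- rep(seq_len(n_templates), each = copies)
  copy_no <- rep(seq_len(copies), times = n_templates)
  ids <- sprintf("%s_t%02d_c%02d", templates$chrom[idx],
                 templates$template[idx], copy_no)
  bases <- templates$sequence[idx]
  quals <- lapply(nchar(bases), function(L) rep(40L, L))
  reads <- read_set(ids, bases, quals)

  truth <- list(
    source = src_name,
    chromosomes = data.frame(name = chrom_name, source_start = chrom_start,
                             source_end = chrom_start + chrom_length - 1L,
                             stringsAsFactors = FALSE),
    templates = templates,
    expected_n_reads = n_templates * copies,
    expected_n_unique = n_templates,
    expected_count = copies,
    expected_redundancy_rate_pct =
      redundancy_rate(n_templates * (copies - 1L), n_templates),
    covered_intervals = template_union_intervals(templates, chrom_name))
  res <- structure(list(reference = reference, reads = reads, truth = truth),
                   class = "synthetic_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(reference, file.path(out_dir, "reference.fasta"))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  res
}

# Draw clip templates per chromosome, redrawing any template that contains or
# is contained in an already-accepted one so the final set is pairwise
# substring-free.
draw_templates <- function(reference, per_chrom, len_range,
                           max_attempts = 10000L) {
  rows <- list()
  accepted <- character(0)
  attempts <- 0L
  for (i in seq_len(nrow(reference))) {
    chrom <- reference$name[i]
    cseq <- reference$sequence[i]
    k <- 0L
    while (k < per_chrom) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_seqrunqc("could not draw a substring-free template set",
                      "synthetic_generation_error")
      len <- sample(seq(len_range[1], len_range[2]), 1L)
      start <- sample.int(nchar(cseq) - len + 1L, 1L)
      tmpl <- substr(cseq, start, start + len - 1L)
      clash <- length(accepted) &&
        (any(stringi::stri_detect_fixed(accepted, tmpl)) ||
           any(stringi::stri_detect_fixed(tmpl, accepted)))
      if (clash) next
      k <- k + 1L
      accepted <- c(accepted, tmpl)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, template = k, start = start, end = start + len - 1L,
        length = len, sequence = tmpl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Union of template clip windows per chromosome, as 1-based closed intervals.
template_union_intervals <- function(templates, chrom_names) {
  out <- lapply(chrom_names, function(nm) {
    t <- templates[templates$chrom == nm, , drop = FALSE]
    if (nrow(t) == 0)
      return(data.frame(start = integer(0), end = integer(0)))
    t <- t[order(t$start, t$end), , drop = FALSE]
    starts <- t$start[1]; ends <- t$end[1]
    for (i in seq_len(nrow(t))[-1]) {
      if (t$start[i] <= ends[length(ends)] + 1L) {
        ends[length(ends)] <- max(ends[length(ends)], t$end[i])
      } else {
        starts <- c(starts, t$start[i]); ends <- c(ends, t$end[i])
      }
    }
    data.frame(start = starts, end = ends)
  })
  names(out) <- chrom_names
  out
}

#' Split a read set into two interleaved halves
#'
#' Alternates reads between the two halves, so a fixture emitted as blocks of
#' identical copies sends half of each template's copies to each side —
#' producing two runs whose unique sets overlap completely.
#'
#' @param reads A `read_set` with an even number of reads.
#' @return List with `run1` and `run2` read sets.
#' @export
split_halves <- function(reads) {
  n <- n_reads(reads)
  if (n %% 2L != 0L)
    stop_seqrunqc("interleaved split requires an even read count",
                  "split_error")
  odd <- seq(1L, n, by = 2L); even <- seq(2L, n, by = 2L)
  list(run1 = read_set(reads$read_id[odd], reads$bases[odd], reads$quals[odd]),
       run2 = read_set(reads$read_id[even], reads$bases[even],
                       reads$quals[even]))
}

#' Random read-set instance with known deduplication truth
#'
#' Property-test generator: draws random templates, optionally plants a
#' fraction of them as proper substrings of other templates, and emits a
#' random number of copies of each. The recorded truth (expected unique
#' count and counters) is derivable independently with a brute-force scan.
#'
#' @param n_templates Number of base templates.
#' @param length_range Template length range (containment-planted templates
#'   are shorter than their container).
#' @param copy_range Copies emitted per template.
#' @param containment_fraction Fraction of templates planted as substrings.
#' @param seed Integer seed.
#' @return List with `reads` (`read_set`) and `truth` (template table and
#'   `expected_n_unique`).
#' @export
random_instance <- function(n_templates = 20L, length_range = c(5L, 40L),
                            copy_range = c(1L, 5L),
                            containment_fraction = 0, seed = 1L) {
  set.seed(seed)
  n_planted <- floor(n_templates * containment_fraction)
  n_free <- n_templates - n_planted
  free <- character(0)
  while (length(free) < n_free) {
    len <- sample(seq(length_range[1], length_range[2]), 1L)
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    clash <- length(free) &&
      (any(stringi::stri_detect_fixed(free, cand)) ||
         any(stringi::stri_detect_fixed(cand, free)))
    if (!clash) free <- c(free, cand)
  }
  planted <- character(0)
  if (n_planted > 0) {
    hosts <- sample(free, n_planted, replace = TRUE)
    planted <- vapply(hosts, function(h) {
      L <- nchar(h)
      len <- sample(seq_len(max(1L, L - 1L)), 1L)
      s <- sample.int(L - len + 1L, 1L)
      substr(h, s, s + len - 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  templates <- c(free, planted)
  copies <- sample(seq(copy_range[1], copy_range[2]),
                   length(templates), replace = TRUE)
  bases <- rep(templates, times = copies)
  perm <- sample.int(length(bases))
  bases <- bases[perm]
  reads <- read_set(paste0("r", seq_along(bases)), bases,
                    lapply(nchar(bases), function(L) rep(40L, L)))
  # expected truth by construction: planted templates (and their copies)
  # collapse into free templates; planted duplicates of free templates or of
  # each other are resolved by the brute-force relation, so recompute the
  # survivor set naively over the distinct strings
  distinct <- unique(templates)
  is_contained <- vapply(distinct, function(s)
    any(s != distinct & stringi::stri_detect_fixed(distinct, s)),
    logical(1), USE.NAMES = FALSE)
  list(reads = reads,
       truth = list(templates = templates, copies = copies,
                    expected_n_unique = sum(!is_contained),
                    expected_n_reads = length(bases)))
}
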