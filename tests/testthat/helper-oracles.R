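# Independent brute-force oracles. These deliberately share no code with the
# package internals: containment is decided by pairwise substring scans and
# depth by a naive per-base loop.

# O(n^2) deduplication oracle: distinct strings, survivors = strings not a
# proper substring of any other distinct string; each removed string's
# multiplicity credited to its longest (ties: lexicographically smallest)
# surviving container.
oracle_dedup <- function(bases) {
  n_input <- length(bases)
  tab <- table(bases)
  seqs <- names(tab)
  mult <- as.integer(tab)
  k <- length(seqs)
  contained <- rep(FALSE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && nchar(seqs[j]) > nchar(seqs[i]) &&
          grepl(seqs[i], seqs[j], fixed = TRUE)) {
        contained[i] <- TRUE
        break
      }
    }
  }
  surv <- seqs[!contained]
  count <- mult[!contained]
  names(count) <- surv
  for (i in which(contained)) {
    containers <- surv[vapply(surv, function(s)
      grepl(seqs[i], s, fixed = TRUE), logical(1))]
    best <- containers[order(-nchar(containers), containers)][1]
    count[best] <- count[best] + mult[i]
  }
  n_inclusive <- sum(mult[contained])
  list(uniques = data.frame(sequence = surv, length = nchar(surv),
                            count = as.integer(count),
                            stringsAsFactors = FALSE),
       n_input = n_input,
       n_unique = length(surv),
       n_distinct = k,
       n_inclusive_removed = n_inclusive,
       n_identical_removed = n_input - n_inclusive - length(surv))
}

# Naive per-base depth oracle: walk each record's CIGAR character by
# character, incrementing single positions.
oracle_depth <- function(alignments, scaffolds) {
  depths <- lapply(structure(scaffolds$length, names = scaffolds$name),
                   function(L) integer(L))
  n_mapped <- 0L
  for (i in seq_len(nrow(alignments))) {
    flag <- alignments$flag[i]
    if (bitwAnd(flag, 4L) || bitwAnd(flag, 256L) || bitwAnd(flag, 2048L))
      next
    if (alignments$rname[i] == "*" || alignments$cigar[i] == "*") next
    pos <- alignments$pos[i]
    ops <- regmatches(alignments$cigar[i],
                      gregexpr("[0-9]+[A-Za-z=]", alignments$cigar[i]))[[1]]
    cursor <- pos
    for (tok in ops) {
      len <- as.integer(sub("[A-Za-z=]$", "", tok))
      op <- sub("^[0-9]+", "", tok)
      if (op %in% c("M", "=", "X")) {
        for (p in cursor:(cursor + len - 1L))
          depths[[alignments$rname[i]]][p] <-
            depths[[alignments$rname[i]]][p] + 1L
        cursor <- cursor + len
      } else if (op %in% c("D", "N")) {
        cursor <- cursor + len
      }
    }
    n_mapped <- n_mapped + 1L
  }
  list(depths = depths, n_reads_mapped = n_mapped)
}

# Brute-force cross-containment: for each sequence of `a`, is there any
# sequence of `b` equal to it, containing it, or contained in it?
oracle_cross_overlap <- function(a, b) {
  vapply(a, function(s) {
    any(vapply(b, function(t)
      s == t || grepl(s, t, fixed = TRUE) || grepl(t, s, fixed = TRUE),
      logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random read sequences with lengths in [lmin, lmax]; short lengths and a
# small alphabet make accidental containment common, which is the point.
random_bases <- function(n, lmin = 5L, lmax = 40L) {
  lens <- if (lmin == lmax) rep(lmin, n)
          else sample(seq(lmin, lmax), n, replace = TRUE)
  vapply(lens, random_dna, character(1))
}

random_read_set <- function(n, lmin = 5L, lmax = 40L) {
  bases <- random_bases(n, lmin, lmax)
  seqrunqc:::read_set(paste0("r", seq_len(n)), bases,
                      lapply(nchar(bases), function(L)
                        sample(0:41, L, replace = TRUE)))
}

# Random SAM-like alignment instance over 1-3 scaffolds with random CIGARs
# (M/I/D/S ops), plus some unmapped/secondary/supplementary records.
random_alignment_instance <- function(max_records = 50L) {
  n_scaf <- sample(1:3, 1)
  scaffolds <- data.frame(
    name = paste0("s", seq_len(n_scaf)),
    length = sample(50:200, n_scaf, replace = TRUE),
    sequence = NA_character_, stringsAsFactors = FALSE)
  n_rec <- sample(0:max_records, 1)
  recs <- lapply(seq_len(n_rec), function(i) {
    j <- sample(n_scaf, 1)
    L <- scaffolds$length[j]
    flag <- sample(c(0L, 0L, 0L, 16L, 4L, 256L, 2048L), 1)
    if (bitwAnd(flag, 4L))
      return(data.frame(flag = flag, rname = "*", pos = 0L, cigar = "*",
                        usable = FALSE, stringsAsFactors = FALSE))
    n_ops <- sample(1:4, 1)
    ops <- sample(c("M", "M", "M", "I", "D", "S"), n_ops, replace = TRUE)
    lens <- sample(1:10, n_ops, replace = TRUE)
    ref_span <- sum(lens[ops %in% c("M", "D")])
    if (ref_span == 0 || ref_span > L) { ops <- "M"; lens <- 1L; ref_span <- 1L }
    pos <- sample.int(L - ref_span + 1L, 1)
    data.frame(flag = flag, rname = scaffolds$name[j], pos = pos,
               cigar = paste0(lens, ops, collapse = ""), usable = TRUE,
               stringsAsFactors = FALSE)
  })
  alignments <- if (n_rec == 0)
    data.frame(flag = integer(0), rname = character(0), pos = integer(0),
               cigar = character(0), usable = logical(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, recs)
  list(scaffolds = scaffolds, alignments = alignments)
}
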