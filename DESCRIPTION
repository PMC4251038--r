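Package: seqrunqc
Title: Run-Level Statistics, Genome Coverage and Inter-Run Overlap for NGS Read Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Preliminary analysis of next-generation sequencing runs: FASTQ
    preprocessing (adapter and quality-end trimming, N-read removal), exact
    deduplication of reads into unique sequences by removing identical and
    inclusive (substring-contained) reads with redundancy-rate statistics,
    per-base genome coverage from SAM alignments with breadth, depth and
    evenness summaries and scaffold-level histograms, and comparison of two
    sequencing runs via exact identity/containment overlap of their unique
    sequence sets. Includes a seeded synthetic-read generator with recorded
    ground truth for validation, an internal exact-match aligner for
    alignment-free testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stringi,
    jsonlite,
    optparse,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
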