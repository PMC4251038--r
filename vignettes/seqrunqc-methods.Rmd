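---
title: "Methods: run statistics, genome coverage and inter-run overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run statistics, genome coverage and inter-run overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqrunqc)
```

## The model

`seqrunqc` treats a sequencing run as a multiset of reads and asks three
questions about it with exact string and interval arithmetic — no
probabilistic model, no mismatch tolerance.

**Redundancy.** After cleaning, two reads are *identical* when they match
100% and have equal length; a read is *inclusive* when its sequence is an
exact proper substring of a longer read, in which case only the longest
read is kept as the unique read. The unique sequences that survive carry a
copy number: their own multiplicity plus the multiplicities of every read
collapsed into them. The redundancy rate is

$$\mathrm{redundancy\ rate\ (\%)} = \frac{\#\,\mathrm{redundant\ reads}}
{\#\,\mathrm{unique\ cleaned\ reads}} \times 100,$$

deliberately normalized by the *unique* count, so a run of one sequence
repeated ten times has a rate of 900%, not 90%. For fixed-length reads the
identical and inclusive notions coincide (a proper substring is strictly
shorter), so identical-only and full deduplication give the same unique
count — a useful internal consistency check that the test suite asserts on
fixed-length instances.

**Coverage.** From each usable alignment (FLAG without 0x4/0x100/0x800,
RNAME and CIGAR present), the CIGAR string is walked: M, `=` and X
operations cover reference bases, D and N advance the reference cursor
without covering, and I, S, H and P consume no reference. Depth arrays are
accumulated per scaffold with a difference-array (+1/−1 at interval
bounds, then a cumulative sum), which the tests verify against a naive
per-base loop. Then, for a reference sequence of length $L$ with $c$
positions of depth ≥ 1 and $m$ total mapped bases:

$$\mathrm{breadth} = 100\,c/L \qquad \mathrm{depth} = m/L \qquad
\mathrm{evenness} = \sigma_b/\bar b,$$

where $\sigma_b$ and $\bar b$ are the standard deviation and mean of the
per-scaffold breadths. Smaller evenness means more even representation of
scaffolds; 0 means every scaffold has the same breadth.

**Overlap between runs.** Each run is cleaned and deduplicated
independently; a unique sequence of one run *overlaps* when it is identical
to, a substring of, or a superstring of some unique sequence of the other
run. "Total overlapping reads" is count-weighted: the cleaned-read mass
carried by the overlapping uniques. The cross-run union of both overlapping
sets, with identical sequences merged and inclusive ones collapsed onto
their longest container, gives the number of unique overlapping sequences
from both runs; for variable-length runs this can exceed either run's own
count, because each side can contribute survivors the other side only
partially absorbs.

## Committed interpretations

Several points are underdetermined by the definitions above; the package
commits to one reading each and keeps it isolated and documented:

- **Strand.** Identity and containment are tested on the forward strand
  only by default. Reads and their reverse complements are arguably the
  same molecule, so `strand = "both"` (CLI `--both-strands`) also tests
  reverse-complement identity/containment; both modes share all code paths.
- **Containment credit.** When an inclusive read has several surviving
  containers, its copies are credited to the *longest* container, ties
  broken by lexicographically smallest. Any deterministic rule would do;
  this one makes unique-table counts byte-reproducible. All copies of a
  removed sequence count as inclusive redundancy; the surviving sequences'
  excess multiplicity counts as identical redundancy.
- **Read counting in coverage.** Secondary (0x100) and supplementary
  (0x800) records are excluded so a multi-mapping read adds depth (and is
  counted as mapped) exactly once, at its primary locus.
- **D/N advance without cover.** A deletion under the read leaves the
  deleted reference bases uncovered; only aligned bases count as "mapped
  bases". This is isolated in `cigar_reference_intervals()`.
- **Evenness denominators.** Evenness is computed on per-scaffold breadths
  with the population (divide-by-N) standard deviation over *all* scaffolds,
  including uncovered ones. The scaffold-depth SD and mean are reported
  alongside because their ratio is a second, non-equivalent dispersion
  summary; no attempt is made to reconcile the two into one number.
- **Reads that trim to nothing** are dropped and counted separately
  (`n_dropped_short`) rather than kept as empty cleaned reads, so
  `n_raw = n_cleaned + n_dropped_n + n_dropped_short` always holds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q_cutoff` | 20 (Phred) | bases are trimmed from both read ends while the terminal base quality is below this |
| `phred_offset` | 33 | ASCII offset of the FASTQ quality encoding |
| `adapter` | none | 3′ adapter; trimming removes the best match and everything 3′ of it |
| `adapter_min_overlap` | 3 bases | minimum adapter/read-terminus overlap for a trim |
| `adapter_max_error_rate` | 0.1 | maximum mismatch fraction in the matched segment |
| `min_length` | 1 base | cleaned reads shorter than this are dropped |
| `strand` | `"forward"` | whether containment also considers reverse complements |
| `depth_bin_edges` | 1, 2, 4, 10 | upper edges of the finite depth-histogram bins |
| `emit_zeros` | off | include zero-depth positions in the per-base track |

Quality trimming is a simple end-scan (remove while terminal quality is
below the cutoff): it is deterministic, explainable in one sentence, and
exactly matches the counter contracts; partial-sum trimming algorithms can
be substituted behind the same interface. Adapter trimming is disabled by
default because no adapter is universal; when enabled it follows the usual
3′-adapter conventions (full internal match, or terminal prefix overlap of
at least `adapter_min_overlap`, best match = longest, ties leftmost).

Histogram bins are open at the lower end and closed at the higher end, with
a dedicated bin for uncovered scaffolds: breadth in ten 10-percent bins,
depth in $(0,1], (1,2], (2,4], (4,10], (10,\infty)$ by default — edges
chosen to discriminate the shallow end, where "is one more run worth it?"
decisions live. The depth edges are configurable.

## The synthetic-data generator

`make_synthetic_run()` emulates a genome re-sequencing experiment at toy
scale with fully known truth: 10 artificial chromosomes are clipped as
disjoint 150-bp windows from a source genome (by default a seeded random
5-kb sequence, so nothing need ever be downloaded; any user FASTA can be
substituted); 10 templates of 75–100 bp are clipped from each chromosome at
seeded positions; each template is emitted 10 times at constant Q40,
giving 1,000 reads. Templates are drawn one at a time and redrawn whenever
a candidate contains or is contained in an already-accepted template —
per-template rejection reaches the same pairwise-substring-free postcondition
as redrawing whole sets, with far better termination behavior. The recorded
truth (clip coordinates, expected unique counts, expected covered
intervals) is therefore forced by construction: 100 uniques of copy number
10 (redundancy 900%), and per-chromosome covered positions equal to the
union of clip windows.

`split_halves()` alternates reads between two halves; because copies are
emitted in blocks, each half receives exactly 5 copies of every template
and the two "runs" overlap 100% — the designed fixture for the run-to-run
workflow. Deliberately *not* emulated: sequencing errors, quality-score
profiles, paired-end fragment geometry, and coverage biases. Passing tests
on this fixture therefore demonstrate the exactness of the counting
arithmetic, not robustness to noisy reads — on real data, redundancy and
overlap as defined here are lower bounds, since a single sequencing error
breaks exact identity/containment.

`random_instance()` generates adversarial deduplication inputs (random
templates with a planted containment fraction and random copy numbers) for
property tests; its truth is recomputed naively at generation time.

## Numerical and scale choices

All statistics are exact integer arithmetic until the final division;
percentages are rounded to one decimal in the two-run ledger and two
decimals in coverage summaries, matching the conventions of run-level QC
reports. Degenerate inputs are errors, not NaNs: a redundancy rate over
zero unique reads, a zero-length genome, an alignment running past its
scaffold end, and a negative derived count (which can only mean an
inconsistent output block) all raise typed conditions.

The test suite validates every engine against an independent brute-force
oracle — an $O(n^2)$ pairwise substring scan for deduplication, a per-base
loop for depth, a pairwise cross-containment scan for overlap — on hundreds
of randomized instances per engine (read sets up to 200 reads of 5–40 bp,
alignment sets up to 50 records over up to 3 scaffolds, unique sets up to
100 per side). These sizes keep the whole suite under a few minutes on one
CPU while still making accidental containment common, which is where the
engines can break.

## Known limitations

- Exact matching only: one mismatch hides redundancy and overlap. The
  original definitions are exact, and mismatch tolerance would require an
  alignment-scoring model out of scope here.
- The internal aligner is exact-match and forward-strand; it exists to make
  the coverage workflow self-contained and testable, not to replace a real
  aligner on real data (supply a SAM file instead).
- Deduplication is quadratic in the worst case (length-sorted survivor scan
  with C-level substring search); it is sized for run-level QC and
  validation, not for hundred-million-read production deduplication.
- Paired-end runs are handled as independent files; mate consistency is
  not enforced or exploited (compare R1 vs R1, then R2 vs R2).
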