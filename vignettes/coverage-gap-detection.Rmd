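---
title: "Detecting sample-specific sequences from read-coverage gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sample-specific sequences from read-coverage gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapdelta)
```

## The problem

When a transposable element (TE) invades a population, its insertions are
present in recently collected genomes but absent from older samples of the
same species. Given an assembly of a sample *P* (presence) and short reads of
a sample *A* (absence), the sequences specific to *P* — the set P − A — show
up as **coverage gaps** when the reads of A are aligned to the assembly of P:
no read of A can be placed inside a sequence A does not carry. gapdelta
detects these gaps and reconstructs the underlying repetitive sequences
without requiring a curated repeat library, which makes it applicable to
unannotated genomes, museum specimens and non-model organisms. The method
detects presence/absence differences only; it is not designed to detect
quantitative copy-number differences between samples that share a sequence.

## The workflow

1. **Align** reads of A to the assembly of P with a *local* aligner, so that
   reads spanning an insertion junction are soft-clipped and depth stops
   exactly at the junction.
2. **Depth**: per-base coverage; positions consumed by CIGAR M/=/X count,
   deletions consume reference without counting (a gap should not be bridged
   by a deletion-spanning alignment).
3. **Gap calling**: maximal runs with depth at or below a threshold (default
   0, i.e. zero coverage).
4. **Merging**: adjacent gaps separated by at most *d* bp are merged
   (default 100), tolerating sporadic spurious read placements inside a
   true gap.
5. **Length filter**: gaps of at least 1000 bp (inclusive) are retained;
   shorter gaps are dominated by alignment noise.
6. **Bias score** per gap (below).
7. **Clustering**: gap sequences are compared all-vs-all by local alignment
   and single-linkage clustered; clusters with at least 3 members are the
   repetitive candidates (the dispersed insertions of one family), the rest
   are reported as non-repetitive.
8. **Consensus**: each cluster is multiply aligned and summarised by a
   majority-rule consensus.

The outputs are `GD-candidates.fasta` (one consensus per cluster),
`GD-non-repetitive.fasta`, `GD.bed` (coordinates and bias of every retained
gap) and `GD-summary.tsv` (copy number, mean length, consensus length and
median bias per cluster), plus all intermediates.

## The coverage-bias score

Not every coverage gap is a real P-specific sequence: assembly errors,
telomeric/centromeric regions and alignment dead zones also produce gaps.
The score

$$\mathrm{bias} = 2\,\frac{f}{g+f} - 1$$

compares the mean depth *f* over the 10,000 bp flanking the gap on each side
(truncated at contig boundaries) with the genome-wide average depth *g*
(all positions, zeros included). A gap flanked by perfectly ordinary
coverage has bias 0; bias −1 means the flanks themselves are uncovered
(e.g. a telomeric dead zone) and bias near +1 means strongly inflated
flanking coverage (e.g. a collapsed repeat). The score is monotone in *f*,
bounded in [−1, 1], and equals 0 iff *f = g*. A cluster's bias is the
median of its members' biases; candidates with cluster bias near 0 are the
reliable ones. When a gap spans a whole contig both flank windows are
empty; the flank mean is then taken as 0, and the score is undefined (an
error) only in the degenerate case *f = g = 0*.

## The built-in read mapper

To keep the full pipeline and its validation self-contained, gapdelta ships
a deliberately small seed-and-extend local mapper rather than wrapping an
external aligner (externally produced SAM is accepted as an alternative
input and bypasses it):

* **Seeding**: exact k-mer index of the assembly (default k = 17, chosen to
  be specific in multi-megabase genomes yet short enough that 25-bp ancient
  DNA fragments still carry several seeds). k-mers containing N are
  skipped; k below 11 is rejected.
* **Extension**: every candidate diagonal is extended by banded local
  (Smith–Waterman) alignment with match +1, mismatch −4, gap −5 — the
  stringent cost ratio a read mapper needs so that alignments terminate at
  insertion junctions instead of drifting across them on chance matches.
  A placement is accepted when at least half the read aligns and the edit
  distance is at most 10% of the aligned length.
* **Soft-clip rescue**: a read spanning an insertion junction aligns only
  its majority side; the clipped remainder (when ≥ 20 bp) is re-mapped as a
  supplementary placement, exactly as production local aligners emit
  supplementary alignments. Without this, every junction leaves an
  uncovered overhang of up to half a read length and gap boundaries no
  longer coincide with the insertion.
* **Multi-mapping ties**: reads matching several identical repeat copies
  equally well are assigned by a deterministic hash of the read id modulo
  the number of tied loci. This spreads multi-mappers across copies the way
  a production aligner's pseudo-random tie-breaking does, while remaining
  byte-reproducible and input-order invariant. Assigning all ties to the
  lowest coordinate instead was rejected: it piles the entire multi-mapping
  read mass onto the first copy of a family, erasing that copy's coverage
  gap entirely.

Local alignment boundaries are exact only up to chance sequence identity:
if the first bases of an insertion happen to match the template
continuation, any local aligner extends a few bases across the junction.
The test fixtures asserting exact boundaries therefore guard the insert
edges against coincidental matches; pipeline-level results are insensitive
to these ±2-bp effects because the consensus step trims unsupported edge
columns.

## Clustering and consensus

Pairs of gap sequences are aligned locally on both strands (banded, seeded
by their best shared-k-mer diagonal, permissive costs 1/−1/−2 so that
diverged copies still chain) and linked when identity ≥ 80% over at least
50% of the shorter sequence. The published description of this stage does
not state numeric cutoffs, so these defaults are this package's own choice,
exposed as parameters: permissive enough to unify ~20%-diverged copies,
strict enough that unrelated kilobase-scale random sequences essentially
never link (pairs sharing no 15-mer are pruned without alignment, which is
also the reason unrelated pairs report no hit rather than a spurious short
local alignment). Connected components of the hit graph are the
single-linkage clusters; components smaller than 3 go to the
non-repetitive output.

Each cluster is aligned progressively: guide tree from shared-8-mer
distances (average linkage), then banded profile–profile alignment with
affine gaps (match +1, mismatch −1, gap open −2, gap extend −0.5; N is
neutral). The majority consensus emits, per column, the most frequent base;
columns where '-' holds a *strict* majority are omitted; base ties resolve
in the fixed order A < C < G < T; N never outvotes a base. "Simple majority
rule" leaves both tie-breaking and gap handling open, so these two rules
are explicit decisions of this package. Their practical effect is that
junction overhangs — the few bases of flanking sequence individual gap
members drag along — appear in gap-majority columns and are trimmed, which
is why consensus lengths match the true insert exactly even at 1x coverage
where individual gaps overshoot the insertion by up to half a read length.

A `refine_consensus()` operation re-extracts cluster members with 3000 bp
of flanking sequence and re-runs the same MSA/consensus machinery; this
recovers full-length consensi when degraded older copies of a family
attract reads that truncate the primary gaps.

## The simulator and what it does (not) emulate

`simulate_scenario()` reproduces the validation design end to end: a seeded
random template (default 2 Mb), 25 identical copies of a random 5000-bp
insert placed at least 25 kb apart and 10 kb from contig ends (so that
bias flanks never overlap a neighbouring insertion), and reads simulated
*from the template* in three modes:

* **uniform** — error-free tiling reads at fixed stride
  (read length / coverage); deterministic coverage.
* **random** — uniformly placed reads; at 1x some positions are uncovered
  by chance, which is what drives false positives at low coverage.
* **ancient** — lognormal fragment lengths (mean 50 bp, sd 15, truncated to
  [25, 150]), terminal cytosine deamination (C→T at 5' offsets, G→A at 3'
  offsets, probability 0.3 × 0.5^offset), 10% reads from an independent
  random bacterial contaminant, 8% modern contamination and 82% endogenous
  DNA.

Two simulator decisions deserve justification. First, the exact
fragment-length and damage settings of ancient-DNA read simulators are not
standardised; the values above are typical of historical museum specimens
(~50-bp fragments, strong terminal deamination) and are parameters, not
constants. Second, modern contamination is drawn from the insert-free
template: the validation insert is an artificial random sequence, which a
contemporary contaminant genome cannot contain. Drawing it from the
insertion-carrying genome instead would place ~0.4x of short fragments
inside every insertion (8% of 5x), fragmenting the very gaps the
validation measures — a situation that belongs to real invasions, where the
contaminant genuinely carries the TE, and is available through
`reads_ancient(modern_genome = ...)`.

The simulator does **not** emulate indel sequencing errors, platform
quality profiles, paired-end structure, GC bias, or genuine biological
divergence between insert copies. Passing the validation therefore shows
that the detection, clustering and consensus machinery is correct under
clean presence/absence signal and under the aDNA degradations modelled; it
does not bound performance on real degraded libraries mapped with other
aligners.

## Problem sizes and numerical choices

The validation scenarios run on a 2-Mb template rather than a full
~25-Mb chromosome arm. True-positive recovery is template-size independent
(it is a per-insertion property), while false-positive counts at low
coverage grow with genome size; the harness therefore asserts FP = 0 only
in the regimes where the full-scale validation also reports zero (coverage
≥ 5), and treats low-coverage FP counts as size-dependent, not targets.
Ten seeds are used for the stochastic random-placement scenarios.

Other numerical conventions: all intervals are 0-based half-open
(BED-style), with SAM's 1-based coordinates converted at parse time and
nowhere else; the gap-length filter is inclusive (a 1000-bp gap is
retained, a 999-bp gap is not); a position is "in a gap" when depth ≤
threshold; flank windows include whatever positions they cover as-is (no
exclusion of neighbouring gaps — with the 25-kb insertion spacing of the
simulator this cannot matter, and on real data excluding them would bias
*f* upward); the genome mean *g* includes every position, zeros inside
gaps included.

## Known limitations

* The built-in mapper is adequate for the simulated validation and for
  desk-scale data; for large real datasets an external local aligner's SAM
  is the intended input (`run_pipeline(sam = ...)`).
* All-vs-all clustering is quadratic in the number of retained gaps; runs
  producing thousands of gaps (very low coverage on large genomes) are
  slow. The 15-mer prefilter prunes most unrelated pairs.
* Progressive MSA is reliable for the near-identical copies of a recent
  invasion; it is not a general-purpose aligner for deeply diverged
  families.
* Copy-number differences of sequences present in both samples are out of
  scope by design.
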