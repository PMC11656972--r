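# gapdelta

Detect sequences present in one sample's genome assembly but absent from
another sample's short reads — the signature of recent transposable-element
(TE) invasions — without a repeat library.

## Who this is for

Given an assembly of sample *P* (presence) and sequencing reads of sample
*A* (absence), the sequences specific to *P* (the set P − A) appear as
**coverage gaps** when the reads of A are aligned locally to the assembly of
P: reads cannot be placed inside sequence A does not carry. Typical uses are
comparisons of historical/museum specimens against modern assemblies,
geographically separated populations, or any two samples suspected to
differ by recent insertions. The method detects presence/absence only, not
copy-number differences of shared sequences.

## The method

1. Map reads of A to the assembly of P with a built-in seed-and-extend
   **local** mapper (or supply external SAM / a per-base depth table), so
   that junction-spanning reads are soft-clipped and depth stops exactly at
   insertion boundaries.
2. Call maximal zero-coverage runs, merge gaps separated by ≤ *d* bp
   (default 100), keep gaps ≥ 1000 bp.
3. Score each gap with the coverage bias

   bias = 2·f/(g + f) − 1

   where *f* is the mean depth over the 10-kb flanks of the gap and *g* the
   genome-wide mean depth. Bias 0 flags reliable candidates; values near ±1
   flag artifact-prone regions (uncovered or repeat-inflated flanks).
4. Cluster gap sequences by pairwise local alignment (≥ 80% identity over
   ≥ 50% of the shorter sequence, both strands, single linkage). Clusters
   of ≥ 3 members are repetitive candidates (one cluster per invading
   family); the rest are reported as non-repetitive.
5. Align each cluster (progressive, banded affine) and emit a
   majority-rule consensus per family.

Outputs: `GD-candidates.fasta` (consensus per cluster),
`GD-non-repetitive.fasta`, `GD.bed` (coordinates + bias of every retained
gap), `GD-summary.tsv` (copy number, mean length, consensus length, median
bias per cluster), plus intermediates. The package also bundles the full
validation harness: a simulator of TE-inserted genomes with uniform,
random or ancient-DNA-style read sets (short fragments, terminal
deamination, bacterial and modern contamination), and an evaluator that
scores a run against the simulated truth (TP, FP, consensus length,
similarity).

## Worked example

Simulate a small scenario — a 300-kb template carrying 3 copies of a
5000-bp random insert, with error-free uniform 5x reads from the insert-free
template — and run the pipeline on it:

```r
library(gapdelta)

sc <- simulate_scenario("uniform", coverage = 5, seed = 3,
                        template_bp = 3e5, n_copies = 3)
res <- run_pipeline(sc$assembly, reads = sc$reads, out_dir = "run_out")
summary_report(res)
#>        cluster copy_number mean_length consensus_length median_bias
#> 1 GD_cluster_1           3    4999.667             5000  0.02444323

metrics_row(res, sc$truth)
#>   TP FP_nr FP_r consensus_length similarity_pct
#> 1  3     0    0             5000            100
```

All 3 insertions are recovered as one cluster of 3 members (`copy_number`),
with a 5000-bp consensus identical to the simulated insert
(`similarity_pct` 100) and near-zero coverage bias — the profile of a real
invading family. `mean_length` is the average gap length (4999.7 here: at one junction the
local alignment extended a single chance-matching base into the insert,
shortening that gap by 1 bp); the consensus step trims such edge noise. The same pipeline is available from the shell via the
bundled script (`exec/gapdelta` in the installed package) with verbs
`run`, `simulate` and `evaluate`.

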