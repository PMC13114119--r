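---
title: "Methods: RB-TnSeq essentiality and fitness analysis in rbtnfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RB-TnSeq essentiality and fitness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and data model

`rbtnfit` analyses randomly barcoded transposon insertion sequencing
(RB-TnSeq) screens for mariner-family transposons, which insert only at
TA dinucleotides. The pipeline starts *after* read mapping: its inputs
are gene models, a TA-site index, a barcode→site map, and per-sample
count tables of summed barcode reads per TA site (the "TA tally",
stored as a `SummarizedExperiment` subclass with sites in rows and
samples in columns). Raw read processing, alignment and barcode
extraction are out of scope.

All coordinates are 0-based half-open, and a TA site is identified by
the coordinate of its T on the forward strand. GFF3 and BLAST-tabular
inputs (1-based inclusive) are converted at the readers. Whether an
insertion coordinate refers to the T or the A of the dinucleotide is a
convention that differs between mapping pipelines; standardising on the
T can shift coordinates by one relative to externally produced tables,
which matters only when mixing indices from different sources.

# Gene-terminus exclusion

Insertions near the ends of a gene frequently leave function intact, so
every insertion-density rule operates on the *internal* span of a gene:
TA sites whose strand-aware offset fraction from the 5′ end lies in
`[head_frac, 1 − tail_frac)`, with defaults `head_frac = 0.05`,
`tail_frac = 0.10`. The asymmetry reflects that 3′ truncations are
tolerated more often than 5′ disruptions. Boundary inclusivity is not
dictated by any biology; we fix the half-open convention above (a site
exactly at the 5% mark is internal, one exactly at the 90% mark is not)
and apply the same formula to every gene, including very short ones and
genes at contig ends. Genes whose internal span contains no TA site
carry no evidence in either direction: they are reported in a separate
`no_data` list and are never called essential.

# Essential-gene candidate calling

The caller is deliberately operational rather than model-based, in
three layers:

1. **Zero-insertion list.** Genes whose internal TA sites carry no
   mapped barcode after validation (each barcode must map to exactly
   one site, and that site must be in the TA index).
2. **Repeat masking.** Insertions inside long repeated elements (IS
   elements, transposases) cannot be uniquely mapped, so zero coverage
   there is an artifact. Candidate repeat spans come either from a
   genome self-alignment table (hits retained when alignment length
   > 1000 bp and identity > 90%, strict inequalities by a literal
   reading of the thresholds; the trivial self-diagonal dropped;
   reciprocal duplicates collapsed) or, for simulated bundles, from an
   internal exact-duplicate k-mer screen. Spans are then clustered
   greedily: sorted by length descending, each span joins the first
   cluster whose representative it matches at identity ≥ 0.9 over
   ≥ 0.9 of the shorter sequence, else founds a new cluster. Identity
   is estimated by k-mer containment (k = 11) and refined by an exact
   pairwise alignment whenever the estimate falls within ±5 points of
   the threshold; the estimator is deterministic, so cluster membership
   is invariant to input row order. We guarantee the stated thresholds,
   not the internals of any particular clustering tool. A gene is
   masked only when **fully contained** in a cluster member span;
   partially overlapped genes are kept, since their non-repeat portion
   still yields mappable evidence.
3. **Manual exclusions.** Curated removals are an explicit input list —
   there is no algorithmic rule for them — and a manual tag absent from
   the zero-insertion list is ignored with a warning.

The final core set is `zero − repeat − manual` with union-aware
subtraction. A complementary **expansion rule** admits genes with
insertions at ≤ 5% (inclusive) of internal TA sites, recovering
near-lethal genes whose handful of surviving insertions keeps them off
the zero-insertion list; domains of essential genes that tolerate
insertions have the same signature, so the expanded list trades
specificity for sensitivity.

Cross-strain support uses reciprocal best hits (RBH) on protein
bitscore tables: a pair is emitted when each protein is the other's
top-bitscore hit, ties broken by smaller e-value then lexicographic
subject id (the tie-break is our fixed choice; any deterministic rule
would do). The concordance report intersects, across all comparison
strains, the focal genes whose orthologs are essential everywhere, then
measures how much of that shared core the zero-insertion and expanded
lists capture.

# Fitness scoring

Each replicate animal contributes one paired comparison between an
input sample (typically the pre-gavage library, T0) and an output
sample (feces at the endpoint). Three stages:

**Positional normalization.** Replication biases counts along the
chromosome (origin-proximal DNA is over-represented in growing cells).
We rescale each sample in fixed genomic windows (default
`window_bp = 10000`): counts in a window are multiplied by
`median(window sums) / (window sum)`; zero-sum windows are left alone.
The windowed-median form is our explicit stand-in for "replication-bias
normalization" — the smoothing scale is not critical, and 10 kb is wide
enough to average over gene-level signal while tracking the
origin-to-terminus gradient. Totals before and after are logged.

**Depth-matched resampling.** The input sample is resampled `R = 100`
times as multinomial draws of the *output* sample's depth from the
input site proportions, simulating random loss of barcodes over time;
the per-site mean over draws is the expected input count. This makes
the fold change depth-invariant by construction (up to pseudocount
effects, below 1% for gene sums ≥ 50).

**Per-gene statistics.** Over a gene's internal sites,
`FC = (Σ out + ψ) / (Σ expected-in + ψ)` with ψ = 0.5, reported on the
symmetric signed scale `s = FC` (FC ≥ 1) or `−1/FC`, so a threshold
`|s| > 2` means two-fold in either direction. The p-value is a
two-sided Mann–Whitney test of the observed per-site output counts
against the expected per-site input counts. Among the interpretations
the published description admits (per-site counts, per-barcode counts,
per-animal fold changes), we fix per-site counts with the resampled
input as the reference, and record that choice in output metadata. When
both vectors are shorter than 8 the null distribution of the rank sum
is enumerated exactly over all C(m+n, n) arrangements of the pooled,
possibly tied, values (base R's rank-sum test has no exact branch under
ties); otherwise the normal approximation with the standard tie
correction and no continuity correction is used. Genes without internal
TA sites are flagged, not scored.

**Replicate combination** is by arithmetic means (`mean_s`, `mean_p`)
and a composite rank: the average of the rank by `mean_p` ascending and
the rank by `|mean_s|` descending, average ranks on ties — half-integer
ranks are therefore expected. Genes missing from some replicates are
averaged over the replicates that scored them, with a count logged. No
multiple-testing correction is applied in selection — cutoffs are on
raw p-values for fidelity to the screen design — but callers can add a
Benjamini–Hochberg column with `p.adjust` when using the tables
otherwise. Significance cutoffs (`|mean_s| > 2`, `mean_p < 0.05`) are
strict inequalities applied per direction.

## Null-calibration behaviour

The per-site test is **conservative under the null**, and users should
know why. The observed output counts and the expected input counts
share each site's underlying insertion abundance, which is strongly
heterogeneous across sites in any real library. Under no selection the
two vectors therefore interleave more regularly than exchangeable ranks
would, the rank-sum statistic is under-dispersed relative to its
nominal variance, and null p-values pile toward 1 rather than being
uniform (the neutral benchmark in `fitnessBenchmark("neutral")` reports
the Kolmogorov–Smirnov distance of the null p-values from uniform,
around 0.3 at the default scale). This is a property of comparing
site-paired vectors with an unpaired test, not of the reference: using
a single resampled draw, or averaging p-values over draws, changes
nothing measurable. The practical consequence is loss of power, never
inflated significance — the fraction of truly neutral genes passing the
combined cutoffs in the neutral benchmark is zero — and the fold-change
threshold, not the p-value, is the binding constraint near the null.

# Condition-set refinement and category accounting

A condition's significant set is refined by subtracting genes that are
also significant in (a) the time-matched healthy comparison — their
signal reflects longer gut residence, not the condition — and (b) an
exposure-only broth comparison — their signal reflects the compound
itself rather than the induced host state. Removal is direction-blind
(a control hit in either direction removes the gene from both
directions of the condition set): the published account does not state
direction handling, and direction-blind removal is the conservative
choice; the order — time control first, then exposure control — is
recorded per gene in the audit table, which makes the bookkeeping
`|refined| + |removed| = |condition|` checkable per direction.

COG category fractions divide the number of significant genes carrying
a category by the number of genes in the *genome* carrying it; genes
with several category letters count in each, and unannotated genes are
excluded from all denominators. COG assignment itself retains a domain
hit when its bitscore equals or exceeds that model's own threshold
(inclusive), which makes assignment monotone in the thresholds. TPM
ranking uses the standard length-normalized transform summing to 10⁶
per sample, rank 1 = highest, average ranks on ties.

# The simulator

`simulateLibrary()` emulates the statistical structure of a barcoded
library screen, not its sequence chemistry:

- a single-contig genome with TA sites planted at the configured
  density (8/kb default — mariner screens see a few sites per hundred
  bp) and background sequence scrubbed of accidental TA dinucleotides,
  so the planted index and a fresh scan of the genome agree exactly;
- ~1000 genes of mean length 3 kb; 5% essential (no internal
  insertions placed); per-condition point-mass fitness effects `w`
  (log2 per generation) assigned to named numbers of genes, all other
  genes neutral, insertions in gene termini and intergenic insertions
  neutral regardless of host gene;
- planted repeat families: sequence-identical blocks, each embedding
  one identical gene; barcodes landing in a family are emitted with
  multiplicity equal to its copy number and are removed by validation,
  reproducing the zero-coverage artifact that repeat masking corrects;
- 50,000 barcodes placed uniformly over permitted TA sites with
  exponential initial abundances (library skew);
- per replicate passage: one multinomial bottleneck of `B = 1e5` cells,
  deterministic exponential growth `2^(w·G)` with `G = 10`, one
  multinomial sequencing draw of `D = 2e6` reads. Growth noise is
  subsumed into the bottleneck — the minimal model that reproduces
  overdispersion across animals; every emitted column sums exactly to
  `D`.

Defaults are desk-scale but informative; 5 replicates matches the
smaller of the two experiment arms the design emulates. What the
simulator does *not* model: sequencing errors, PCR chimeras, barcode
collisions, per-site insertion-preference heterogeneity (real libraries
show per-gene insertion counts ranging over three orders of magnitude;
a placement-weight option would be a free distributional choice we have
not taken), strand effects, polar effects in operons, or any host
response. Passing the recovery benchmarks therefore shows the
*statistics* behave as designed under the modelled noise, not that the
pipeline is robust to every artifact of real libraries.

Unit tests run reduced configurations (40–100 genes, 0.8–1 kb genes,
1.5–6 k barcodes); the recovery and calibration benchmarks
(`fitnessBenchmark()`, also exercised by `scripts/acceptance.R`) run
the full default scale: 1000 genes, 50 planted at `w = −1`, 5
replicates, 100 resamples.

# Numerical and degenerate-input choices

- Exact rank-sum enumeration below length 8 on both sides (C(14,7) =
  3432 arrangements at worst); normal approximation with tie correction
  above; a degenerate pooled vector (all values equal) returns p = 1.
- Pseudocount ψ = 0.5 bounds `|s|` for genes with zero output counts.
- Resampling, passage and library generation take explicit integer
  seeds; the pipeline driver fans one global seed out deterministically
  to stage seeds, so identically configured runs are byte-identical.
- Windows with zero counts are not rescaled (factor 1); a zero-depth
  input sample is an error, an all-zero sample *column* in a loaded
  bundle is accepted and flagged.
- Greedy clustering length-sorts with a contig/start tie-break, making
  it independent of input order; identical-length spans tie-break
  lexicographically.
- Manual exclusions outside the zero-insertion set warn and are
  ignored; subtraction of overlapping exclusion sets never
  double-counts.

# Known limitations

- Essentiality calls are candidate lists, not proofs: genes whose
  disruption is merely very costly, genes rescued by neighbours, and
  essential genes with dispensable domains all blur the boundary; the
  expansion rule and the no-data list exist to make those cases
  visible rather than to resolve them.
- The conservative null calibration above means borderline fitness
  determinants (true `|w|` just over the detection limit) are missed
  more often than a perfectly calibrated test would miss them.
- The positional normalization is a stand-in with a fixed functional
  form; screens with sharp local coverage artifacts (prophages, large
  deletions) may need a different window scale.
- Repeat masking relies on the provided self-alignment (or the internal
  exact-duplicate screen, which only finds near-identical copies);
  diverged repeat families below the identity thresholds are not
  masked.
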