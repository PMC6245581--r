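---
title: "Methods: co-occupancy analysis of ChIP-seq peak compendia"
author: "chipcooc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy analysis of ChIP-seq peak compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcooc)
```

# The problem

A ChIP-seq experiment yields a set of genomic intervals ("peaks") where one
transcription-related factor binds in one cell type. Public compendia hold
hundreds of such peak sets per species. `chipcooc` integrates them to ask five
questions: which experiments bind the same places (co-occupancy); where
factors sit relative to gene transcription start sites (TSS preference);
whether densely bound regions ("transcription hotspots") are shared across
cell types or cell-type specific; which exact combinations of factors co-bind
more loci than chance allows; and whether any factor's binding sites are
enriched for disease-associated loci from GWAS catalogs.

All coordinates inside the package are 0-based half-open. Readers convert on
entry, writers on exit, so BED round trips are coordinate-exact.

# The occupancy matrix

All peak sets of a dataset are merged into non-overlapping peak-containing
regions; two peaks merge iff they overlap or are bookended (`end == start`),
matching the default of the classical merge tool so the merged-region
granularity is the standard one. The binding matrix has one row per merged
region and one column per experiment; cell (i, j) is 1 iff experiment j has a
peak sharing at least one base with region i. No minimum-overlap fraction is
applied — a single shared base counts, which is the natural choice when the
regions themselves are unions of peaks.

Pearson correlation between binary columns (equivalently the phi coefficient)
measures co-occupancy. Constant columns (an all-zero experiment kept after a
warning) get correlation 0 with everything else and 1 with themselves, so no
sample silently disappears. Experiments are clustered by complete-linkage
hierarchical clustering on the Euclidean distances between correlation rows,
and the dendrogram leaves are re-ordered by optimal leaf ordering — the
dynamic program over subtree orientations that minimizes the summed distance
between adjacent leaves. The ordering is exact; for more than 2,000 leaves
(far above compendium scale) the package falls back to the raw dendrogram
order with a warning. Reference tracks (TSS positions, optionally CpG
islands) are overlay columns: they never create regions and are excluded from
correlation, density and enrichment computations. We cluster experiments only
and display tracks on top; the alternative (clustering tracks as
pseudo-experiments) would distort the experiment dendrogram.

# TSS annotation and location profiles

A TSS table carries one point per gene — the median of its transcript start
positions, taking the lower of the two middle values for an even count so the
reported TSS is always an observed transcript start. Each region or peak is
annotated with the nearest TSS: unsigned distance is 0 when the region
contains the TSS, else the distance from the TSS to the nearest covered base
(`end - 1`, not the half-open end — the off-by-one is deliberate and
documented). The sign is gene-strand-aware: negative = upstream (5') of the
gene, positive = downstream. Equidistant TSS are resolved to the
lexicographically smaller gene id, which makes annotation deterministic.
Which signed-distance convention the original tooling used is ambiguous
(`-D a`, `-D b` and `-D ref` all exist in the wild); we standardize on
gene-strand-relative sign because it is the one that makes
"upstream/downstream of the gene" statements meaningful.

Per experiment, the location profile is the triple of fractions of peaks
overlapping (`d == 0`), upstream of (`d < 0`) and downstream of (`d > 0`) the
nearest TSS; peaks on chromosomes without any TSS are excluded from the
denominators and the exclusion is logged. Experiments with more than half
their peaks on one side are set aside as upstream-/downstream-biased; the
rest are displayed sorted by the TSS-overlap fraction. Across species,
factors are matched by case-insensitive symbol equality (CFOS = cFos), the
per-factor summary is the median TSS-overlap fraction with its unscaled
median absolute deviation (a display range, so no 1.4826 consistency factor),
and the comparison reports the Pearson correlation and the ordinary
least-squares fit.

# Hotspots: proximal vs distal density

Regions are split by proximity to the nearest TSS: proximal means
`|d| < 1000` bp, distal `|d| >= 10000` bp, and the band in between belongs to
neither — the two thresholds deliberately leave a gap, keeping both classes
unambiguous. TF density of region i in cell type c is the number
of that cell type's experiments with a peak there divided by the cell type's
experiment count, a value in [0, 1]. Only cell types with more than a
configurable number of experiments (default 30, strict) enter the density
analysis, since density is a proportion and needs a reasonable denominator.

Density profiles across cell types are clustered by k-means: k-means++
(D-squared) seeding from a mandatory seed, Lloyd iterations, `n_init = 10`
restarts keeping the lowest within-cluster sum of squares. The cluster count
is not identified by the underlying analysis, so it is a configuration
parameter with default `k = 6`, in the range the hotspot heatmaps display;
clusters are relabelled by decreasing mean total density so "cluster 1" is
always the strongest hotspot cluster, and a `drop_lowest` switch removes the
large weakly-bound background cluster from summaries. k-means is run per
dataset (species), matching the per-panel presentation of the analysis.

# Combinatorial co-binding

Within a cell type with at least 6 distinct factors (replicate experiments of
a factor are collapsed by peak-set union, because combinations are statements
about factors, not experiments), every region bound by at least one factor
carries exactly one *exact* binding pattern — the precise subset of factors
binding it, one of `2^N - 1` nonempty patterns. Observed pattern counts are
scored against 100 (configurable) randomizations that permute each factor's
bound-region set independently and uniformly while preserving its size, i.e.
all column sums are preserved exactly (asserted on every randomization).
Randomized rows that become empty count as the empty pattern.

For each observed pattern, `z = (observed - null mean)/null sd` and the
p-value is the upper-tail standard-normal probability of z. A 100-draw
empirical rank cannot go below 1/101, while genuinely planted modules sit
hundreds of standard deviations above their null, so the normal tail on the
randomization moments is the only reading that can express such results; the
package carries the tail in log space (`log10_p_raw`) because these p-values
underflow double precision, and ranks results on the log scale. Bonferroni
correction multiplies by the full family `2^N - 1`, counting the patterns
with zero observed regions. Two numerical conventions matter:

* **Degenerate null (sd = 0).** When a pattern's count is identical in every
  randomization, the normal tail is undefined. The package falls back to the
  add-one empirical rank: `p = 1/(n_rand + 1)` if the observed count exceeds
  the constant null count, else `p = 1`. Treating such patterns as `p = 0`
  would declare a single-region multi-factor coincidence infinitely
  significant even though 100 randomizations cannot resolve probabilities
  below 1/101; with the fallback, planted-module recovery is exact (the
  module outranks every coincidence) and calibration on unstructured data
  holds.
* **Only enrichment is tested.** Depletion is out of scope; the analysis
  reports over-represented combinations only.

At small, densely bound universes, single-factor patterns can be strongly
"enriched" too (a factor's exclusive regions are diluted by collisions under
randomization), so single-factor rows in the output are expected and the
interesting biology is in the multi-factor patterns.

# GWAS overlap

GWAS hits are points (SNP positions, 1-based in catalog files, converted on
read); an optional symmetric window (default 0) widens them — linkage
expansion is out of scope. The test universe is the dataset's merged regions
(every region bound by at least one experiment), counted at region level;
the universe is not stated by the analysis we reproduce, and this is the
natural one for its matrix formulation. For each experiment: `n` bound
regions, `k` of them containing at least one hit, tested against `K` marked
regions of `U` with the upper-tail hypergeometric probability `P(X >= k)`,
computed in log space (lchoose + log-sum-exp suffix accumulation) so extreme
tails remain exact; Bonferroni correction is by the number of experiments
tested. A region with several hits counts once for the test but keeps its
full trait set for the per-trait breakdown of significant experiments.

# The synthetic compendium

`simulate_dataset()` generates a full, reproducible dataset with planted
ground truth. Defaults (all chosen once, for realism at desk scale):

* genome: 3 chromosomes x 10 Mb, 1,000 genes, TSS spacing >= 2 kb, strands
  Bernoulli(1/2);
* peak widths log-normal with median 300 bp and sigma_log 0.4, the typical
  scale of TF ChIP-seq peaks;
* distal offsets log-uniform on [1 kb, 100 kb] so both the 1 kb and the 10 kb
  proximity thresholds are exercised on both sides of the TSS;
* eight factor archetypes x 3 cell types (24 experiments, about 19,000 merged
  regions): two promoter-biased factors (RNAPII-like), a shared distal factor
  reusing one peak set in every cell type (CTCF-like), one
  downstream-biased (ZNF274-like) and one upstream-biased
  (RNA-polymerase-III-like) factor, and three cell-type-specific distal
  factors that form a planted exclusive co-binding triple of 1,000 regions
  per cell type.

Peak placement is validated by rejection resampling against the *realized*
nearest-TSS sign, so archetype location fractions are recovered to binomial
accuracy (the acceptance suite checks ±0.02 at 10,000 peaks). Exclusive
module regions are avoided (with a 1 bp margin, so bookended merges are also
impossible) by every peak outside the module, which is what "bound by nothing
else" requires. Cell-type-specific distal factors draw their distal peaks
from a per-cell-type enhancer pool, so factors of the same cell type share
distal regions while cell types share none — this is what makes distal
binding cluster by cell type, as real compendia show. Planting the module
per cell type (rather than one shared region set) lets the module factors
double as that cell-type-specific structure; a shared module would instead
mimic the CTCF-like behaviour already covered. Replicates resample 90% of
the first replicate's peaks and draw the rest fresh.

The GWAS table places a binomial share of hits inside the planted factor's
peaks such that the per-bp hit density there exceeds the rest of the genome
by the target ratio (default 3); ratio 1 reduces exactly to a uniform table,
which is the calibration case. Traits come from a small fixed vocabulary.

What the generator does **not** emulate: read-level noise and peak-calling
artifacts, chromatin context (GC, mappability, accessibility), linkage
structure among GWAS hits, unbalanced factor coverage across cell types, and
genome-scale gene-density variation. Passing tests on synthetic data
therefore validate the statistical machinery and its calibration, not the
biology of any particular compendium.

# Pipeline, seeds and scale

`run_stage()` executes `simulate`, `matrix`, `heatmap`, `tss`, `hotspots`,
`combos`, `gwas` or `all` under a flat key=value config; each stage checks
its upstream artifacts and names the stage to run first when they are
missing. Every stochastic stage derives its own seed deterministically from
the single config seed and the stage name, so stages are independently
re-runnable and two runs with the same seed produce byte-identical text
artifacts (TSV/BED/MTX/JSON; PNG heatmaps are display artifacts and are not
part of the reproducibility contract). Each run echoes the fully resolved
config next to its outputs and writes a machine-readable `summary.json`.

Default thresholds mirror compendium scale (cell types with more than 30
experiments, at least 6 distinct factors, 100 randomizations, alpha 0.05).
The bundled synthetic demo has 8 experiments per cell type, so the worked
examples and the acceptance script set `min_experiments_per_cell_type = 5`;
that is a statement about the demo's size, not about the method. The default
synthetic run (about 19,000 regions x 24 experiments) completes in well under
a minute on one CPU; the test suite's heaviest checks (100-seed
planted-module recovery and the exhaustive hypergeometric sweep) take a few
minutes in total.

# Known limitations

* The co-binding p-value is a normal-tail approximation on 100 randomization
  moments; it is accurate for the extreme signals the analysis targets but
  should not be read as an exact tail probability near the significance
  boundary. Raising `n_rand` tightens it.
* The GWAS universe choice (merged regions of the dataset) makes results
  comparable across experiments within a dataset but not across datasets with
  different region universes.
* Optimal leaf ordering is exact but cubic-ish in the leaf count; beyond
  2,000 leaves the package intentionally degrades to dendrogram order.
* Nearest-TSS annotation assumes a point TSS per gene; promoter extent and
  bidirectional promoters are not modelled.
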