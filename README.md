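# chipcooc

Integrative co-occupancy analysis of transcription-factor ChIP-seq peak
compendia.

Public compendia hold hundreds of TF ChIP-seq peak sets per species. For
anyone integrating them — regulatory genomicists, epigenomics core analysts —
`chipcooc` answers five questions end to end:

1. **Co-occupancy.** Merge all peaks into non-overlapping regions, build the
   binary occupancy matrix `B` (M regions x N experiments,
   `B[i,j] = 1` iff experiment j has a peak in region i), correlate columns
   (Pearson on binary data = the phi coefficient,
   `(M·n11 − n1·n2) / sqrt(n1(M−n1)·n2(M−n2))`) and cluster the correlation
   matrix with complete linkage plus exact optimal leaf ordering.
2. **TSS preference.** Annotate each peak with its nearest gene TSS and
   strand-aware signed distance d (negative = upstream), giving per-experiment
   fractions (f_up, f_tss, f_down); compare factors across species.
3. **Hotspots.** Split regions into promoter-proximal (|d| < 1 kb) and distal
   (|d| ≥ 10 kb), compute TF density per cell type (fraction of the cell
   type's experiments bound), and k-means-cluster density profiles to separate
   shared promoter hotspots from cell-type-specific distal ones.
4. **Combinatorial co-binding.** Per cell type with ≥ 6 factors, count the
   exact factor subset binding each region (one of 2^N − 1 patterns) and score
   it against 100 column-sum-preserving randomizations:
   `z = (observed − null mean)/null sd`, upper-tail normal p, Bonferroni by
   2^N − 1.
5. **GWAS overlap.** Per experiment, test the bound regions' overlap with
   GWAS catalog loci by the upper-tail hypergeometric probability
   `P(X ≥ k)`, `X ~ Hypergeom(U, K, n)`, Bonferroni-corrected.

A synthetic-compendium generator with planted ground truth (factor location
archetypes, a CTCF-like shared factor, an exclusive co-binding triple, a
GWAS-enriched factor) makes every stage testable, and a staged pipeline
driver ties it all together.

## Worked example

```r
library(chipcooc)

sim <- simulate_dataset(42)                       # planted ground truth
bm  <- build_binding_matrix(sim$manifest, sim$peaks)
bm
#> BindingMatrix: 18960 regions x 24 experiments

cc <- cluster_correlation(correlate_binding(bm))
grep("CTCFL", cc$leaf_order, value = TRUE)
#> "CTCFL.cellC.1" "CTCFL.cellB.1" "CTCFL.cellA.1"   # adjacent: one cluster
```

The three CTCF-like experiments — the only factor sharing one peak set across
cell types — sit adjacent in the optimally ordered heatmap, exactly as a
CTCF/cohesin cluster does in real compendia.

```r
res <- combination_enrichment(sim$manifest, sim$peaks, seed = 7)
head(res[res$cell_type == "cellA", c("pattern", "observed", "null_mean", "z", "p_bonf")], 3)
#>           pattern observed null_mean     z p_bonf
#> 1 MODA+MODB+MODC      1142      91.7 112.2      0
#> 2          DOWNB      1061     313.8  58.5      0
#> 3          CTCFL      1120     320.8  48.8      0
```

The planted exclusive triple is the top pattern: 1,142 regions bound by
exactly {MODA, MODB, MODC} against a null expectation of ~92, i.e. 112
standard deviations above the randomization null (the Bonferroni p underflows
double precision; `log10_p_raw` in the full table carries the log-scale
value).

```r
marks <- mark_gwas_regions(bm$regions, sim$gwas)
head(test_gwas_overlap(bm, marks)[, c("experiment_id", "n", "k", "fraction", "p_bonf")], 3)
#>   experiment_id    n   k fraction   p_bonf
#> 1 CTCFL.cellA.1 1626 115   0.0707 4.95e-19
#> 2 CTCFL.cellB.1 1626 115   0.0707 4.95e-19
#> 3 CTCFL.cellC.1 1626 115   0.0707 4.95e-19
```

The planted GWAS-enriched factor tops the overlap test: 115 of its 1,626
bound regions (7.1%) contain a disease-associated locus, against a 2.85%
background rate (`mean(marks$marked)`).

The same analyses run as a pipeline:

```sh
Rscript inst/cli/chipcooc.R all --out out --seed 42 min_experiments_per_cell_type=5
```

which writes the occupancy matrix (`matrix/`), correlation and leaf order
(`heatmap/`), TSS annotations and location profiles (`tss/`),
proximal/distal correlations, TF density and hotspot clusters (`hotspots/`),
the combination table (`combos/`), the GWAS results (`gwas/`), a resolved
config echo and a `summary.json`.

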