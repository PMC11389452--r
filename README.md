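# bvcr — bivalent chromatin region analysis

`bvcr` is an R package for analysing **bivalent chromatin regions (BvCR)**:
genomic regions where ChIP-seq peaks of the activating H3K4me3, the
repressive H3K27me3 and the enhancer-associated H3K27ac histone marks
mutually overlap. Such regions keep genes poised between activation and
silencing; in CD4⁺ T cells they coordinate the DNA damage response, and the
chromatin-binding oncoprotein survivin preferentially colocalizes with them.
The package is aimed at epigenomics analysts who have per-mark peak tables
(BED-like, with tag counts) and want the full downstream analysis without
any bespoke scripting.

## What it computes

* **Region calling** — `merge_connected()` merges peaks that share ≥ 1 base
  (touching intervals do *not* merge) and `call_bvcr()` retains merged
  footprints containing every required mark (all three by default; the
  methyl-only definition via `required_marks`).
* **Dominance** — the *dominant mark* of a region is the mark with the
  largest share of its normalized tags (tags per 10⁷ mapped,
  `normalize_tags()`):

  ```
  pct_m = 100 · T_m / (T_K4me3 + T_K27me3 + T_K27ac),   dominant = argmax_m pct_m
  ```

  with survivin colocalization flags (≥ 1 bp overlap), stratified frequency
  tables with a chi-square homogeneity test, and the pooled two-proportion
  z test for prevalence comparisons.
* **Deposition dynamics** — signed fold changes (negative reciprocal below
  1), percent tag change, *changeable* regions (dominant mark differs
  between conditions), and scale-regions / reference-point profile matrices
  (500 bp body, 2 kb flanks, 50 bp bins → 90 columns by default).
* **Colocalization enrichment** — observed overlap counts (≥ 10% of the
  query interval) versus 15 within-chromosome shuffles, two-tailed p from a
  predictive-SE normal approximation (or empirical), Benjamini–Yekutieli
  q-values, and the filter *overlaps > 5 and q < 0.05*.
* **Regulatory linkage** — enhancers + gene bodies + strand-aware 2-kb
  upstream promoters, region→gene link tables, the strict expression filter
  (base mean > 1, protein-coding), and aggregation onto a hierarchical DNA
  damage response network with per-node dominant marks.
* **Tag–transcription coupling** — a line through the (min, median, max)
  order-statistic anchors of tag change vs transcription change, a
  one-standard-deviation residual inclusion rule, and subgroup Spearman
  correlations (up/down × stratum).
* **Peptide binding** — proteins tiled into 15-mers (step 5, C-terminal
  anchor tile), composition-by-position encoding over a functional-group
  table, a two-hidden-unit neural classifier with training-split
  standardization and C-terminal-cysteine exclusion, and the summaries
  R_bind (fraction of tiles predicted to bind) and M_bind(n) (fraction of
  the 19 × covering-tiles substitutions at position *n* predicted to bind).
* **Synthetic data** — `synth_config()` plus `simulate_*()` generate peak
  landscapes, treatments, expression tables, enhancer links and peptide
  arrays with known ground truth.

## Worked example

```r
library(bvcr)

cfg <- synth_config(n_bvcr = 600, n_decoys_per_mark = 60, n_decoy_survivin = 60)
ls1 <- simulate_peak_landscape(cfg, seed = 7)
bv  <- call_bvcr(ls1$peaks$H3K4me3, ls1$peaks$H3K27me3, ls1$peaks$H3K27ac,
                 survivin = ls1$peaks$survivin)

length(bv)
#> [1] 600
table(bv$dominant)
#>  H3K27ac H3K27me3  H3K4me3
#>      144      187      269
mean(bv$survivin_positive)
#> [1] 0.635
```

All 600 planted loci are called (none of the 180 single-mark decoys
qualifies), the planted 43/33/24 dominance mix and the 0.65 survivin
colocalization are recovered within sampling error. The stratified
dominance table and its homogeneity test:

```r
tab <- dominance_frequency_table(bv)
round(tab$percents, 1)
#>      dom
#> strat H3K4me3 H3K27me3 H3K27ac
#>    S-    43.8     29.2    26.9
#>    S+    45.4     32.3    22.3
round(tab$p_value, 3)
#> [1] 0.42
```

(p = 0.42: the dominance distribution does not differ between survivin
strata, as planted.) The worked prevalence comparison — dominance shifts
among survivin-positive (325/4068) versus survivin-negative (205/2131)
regions:

```r
res <- compare_prevalence(325, 4068, 205, 2131)
c(z = res$z, p = res$p_value)
#>           z           p
#> -2.18086788  0.02919319
```

## Documentation

The methods vignette (`vignettes/bivalent-chromatin-methods.Rmd`) documents
the models, every tunable parameter with its default and rationale, the
synthetic generator's assumptions and limits, and the numerical choices
(tie-breaks, pseudocounts, degenerate inputs).
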