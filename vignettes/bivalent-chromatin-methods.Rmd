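---
title: "Bivalent chromatin region analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivalent chromatin region analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvcr)
```

## The scientific problem

Bivalent chromatin regions (BvCR) carry both the activating H3K4me3 and the
repressive H3K27me3 histone marks (and in this analysis additionally
H3K27ac), letting a cell keep genes poised between activation and silencing.
`bvcr` implements the full analysis chain around this object for
ChIP-seq-derived peak sets: region calling by mutual peak overlap, per-region
mark dominance, colocalization with the chromatin-binding oncoprotein
survivin, treatment-induced dominance shifts, enrichment against external
region catalogs, linkage of regions to the genes they regulate, a simple
linear coupling of tag change to transcription change, and a compositional
classifier of survivin-binding propensity for protein sequences such as the
BRG1/SWI chromatin-remodeling complex subunits.

Everything is validated against a synthetic data generator with known ground
truth, so the pipeline is testable end to end without any sequencing data.

## Coordinates and region calling

All intervals live in `GRanges` (1-based, closed), the Bioconductor
convention; BED input/output (0-based, half-open) is converted at the I/O
boundary by `read_peaks()` / `write_bed()`. Keeping a single internal
convention removes off-by-one ambiguity from every downstream rule.

Two peaks are *connected* when they share at least one base. Intervals that
merely touch in BED coordinates (`end == start` of the next) share no base
and are **not** connected; `merge_connected()` therefore reduces with a
minimum gap width of zero shared bases and its components are tested against
a per-base brute-force oracle. A merged footprint qualifies as a BvCR when
it contains at least one member peak of every required mark.

Which marks are required is a configuration, not a silent choice: the
default demands all three H3 marks (the deposition analysis reports
H3K27ac-dominant regions, which only exist under the three-mark definition),
while `required_marks = c("H3K4me3", "H3K27me3")` gives the classical
methyl-only bivalency definition.

### Dominance

Per region, normalized tags (tags per 10 million mapped, see
`normalize_tags()`) are summed per mark; the mark with the highest share of
the three-mark total is *dominant*. Exact ties are broken by the fixed
priority H3K4me3 > H3K27me3 > H3K27ac and flagged (`tie_flag`), so
tie-breaking is visible rather than arbitrary. Regions whose three tag sums
are all zero have undefined dominance and are excluded from dominance
statistics.

The chi-square homogeneity test behind `dominance_frequency_table()` uses
the textbook statistic with the convention that cells of an all-zero
category contribute zero, on (strata − 1) × (marks − 1) degrees of freedom
over all three mark categories. On tables with positive margins this equals
`chisq.test()` exactly (asserted in the tests); the convention only matters
for degenerate tables where a mark never dominates.

`compare_prevalence()` is the pooled two-proportion z test without
continuity correction; on the worked example of dominance-shift prevalence
among survivin-positive (325/4068) versus survivin-negative (205/2131)
regions it gives |z| = 2.18 and p = 0.029.

## Deposition dynamics

`signed_fold_change()` reports the pseudocounted ratio when it is at least
1 and its negative reciprocal otherwise, so magnitudes are symmetric around
±1 and the sign encodes direction. The pseudocount (default 1, applied to
both terms) guards empty signal; `tag_pct_change()` similarly guards its
denominator with a pseudocount of 1 normalized tag, because percent change
from an empty region is otherwise undefined. Percent tag change is computed
on per-region per-mark normalized tag sums; a share-point alternative can be
derived from the `pct_*` columns if preferred — the relative change of tag
sums is the default because it is the interpretation consistent with
signed fold changes.

A region is *changeable* when its dominant mark differs between conditions
(`detect_changeable()` recomputes dominance per condition, so the rule is
identical pre and post).

`profile_matrix()` emulates the scale-regions / reference-point score
matrices common in ChIP-seq visualisation: bodies are rescaled to 500 bp
with 2 kb flanks at 50-bp bins (90 columns) by default; body bins average
the track over equal genomic fractions of the region; positions without
track data, including positions clipped at chromosome bounds, score zero.
The reference point is the region midpoint, `floor((start0 + end0) / 2)` in
0-based coordinates. The matrix is linear in the track under the mean
aggregate, which the tests exploit.

## Colocalization enrichment

`enrichment_test()` compares the observed number of query regions overlapped
by a catalog (a query counts when one catalog interval covers at least 10%
of the query's length — applied query-side by default, both sides via
`side = "both"`) against 15 within-chromosome shuffles of the query. Shuffles
preserve chromosome and length and may overlap each other or the original
regions; no exclusion mask is applied.

With 15 shuffles an empirical p-value has a granularity of ~1/16, so the
default p-value uses a normal approximation. The observed count is one new
draw compared against a *sample* estimate of the null, so the correct
standardization is the predictive standard error `sd * sqrt(1 + 1/n)`
rather than `sd` alone; this keeps the test close to nominal level (the
acceptance suite verifies a null false-positive rate at or below 0.08 at
α = 0.05 over 200 simulated datasets). An empirical mode
(`p_method = "empirical"`, add-one corrected) is available. When every
shuffle returns the same count, the test reports p = 1 if the observation
equals it, and otherwise floors the standard deviation at 0.5 counts with a
warning — a count distribution cannot be narrower than its discreteness.

q-values are Benjamini–Yekutieli over catalogs (valid under arbitrary
dependence between catalogs, via `stats::p.adjust`), and the reported
filter requires more than 5 observed overlaps and q < 0.05.

## Regulatory linkage

`build_element_universe()` combines enhancer intervals with gene bodies and
strand-aware promoters, defined as the 2 kb immediately upstream of the TSS
(excluding the TSS base, clipped at chromosome bounds). Links require at
least 1 bp of region–element overlap and keep one row per (region, element,
gene) triple, so genes reached by several regions remain visible.
`filter_expressed()` applies the strict criteria base mean > 1 **and**
protein-coding biotype; sensitivity flags use nominal p < 0.05 per contrast
(configurable — adjusted p-values can be supplied in the p-value columns if
a stricter definition is wanted).

`annotate_ddr_network()` aggregates onto a hierarchical gene→node map:
per node, the connected-gene percentage and the mean per-mark tag
percentage over the regions linked to the node's genes, with the node's
dominant mark the argmax of those means. Genes assigned to several nodes
contribute to every node they occupy: the hierarchy levels of the network
describe overlapping biological assemblies, and restricting a gene to its
most specific node would silently underweight the broader assemblies.

## The quantile-anchored linear model

`minmax_line()` pairs the (min, median, max) *order statistics* of the tag
change with those of the transcription change into three anchors and fits
them by ordinary least squares. Pairing summaries (rather than taking the
observed y at the argmin/argmedian/argmax of x) is the default because the
anchors are meant as distribution-level landmarks; the joint-point
alternative is available via `anchor = "joint"`, and an exact min–max chord
(ignoring the median anchor) via `chord = TRUE`. For collinear data every
variant is exact.

The inclusion rule keeps genes whose absolute residual — computed in the
transcription direction by default, `direction = "x"` inverts the line —
is at most one *population* standard deviation of all residuals. A
tolerance of 1e-12 absorbs floating-point residuals on exactly collinear
input. Spearman correlations (tie-corrected, two-sided) are computed per
(up/down) × stratum cell over the included genes; cells with fewer than 3
genes are undefined. Note that both the residual filter and the direction
split *condition* the sample, so per-cell correlations are not estimates of
the planted copula correlation — the overall coupling is measured with
`split_direction = FALSE`, which is how the recovery checks assert the
planted ρ of 0.6 within ±0.05 at n = 2000.

## Compositional peptide binding

Proteins are tiled into 15-mers at a 5-residue step (10-residue overlap);
when the last regular tile stops short of the C-terminus an extra tile
anchored at `L − 14` is appended so every residue is covered — without it,
`m_bind()` positions near the C-terminus would be unscoreable.

Each tile is encoded composition-by-position: for each of the 15 positions,
the counts of 14 functional groups (one backbone amide per residue plus
side-chain methyl/methylene/methine, aromatic ring, hydroxyl, carboxyl,
amide, sulfhydryl, thioether, guanidinium, imidazole, indole, primary
amine). The residue→group table (`aa_group_table()`) is this package's own
chemical decomposition of the 20 standard side chains; it is a configuration
artifact — any chemically sensible decomposition satisfies the module's
contracts, and the tests depend only on its block structure and
determinism, not on specific entries.

The classifier is a single-hidden-layer feed-forward network with two
hidden units (`nnet`), trained on 90% of the eligible tiles with features
standardized by training-split statistics. Tiles ending in cysteine are
excluded from training (a C-terminal cysteine is a coupling-chemistry
artifact on peptide arrays) but remain scoreable. Because a two-unit net
has local minima, training restarts a few times from small random weights
(`rang = 0.1`) and keeps the lowest training deviance; the split and
restarts are controlled by one seed, so retraining is bit-stable. The
binary label defaults to fluorescence > 10,000 units, the moderate-binding
boundary of the intensity scale (strong > 30,000 ≥ moderate > 10,000 ≥
low > 1,000 ≥ none).

`r_bind()` is the fraction of a protein's tiles predicted to bind;
`m_bind(n)` substitutes position *n* to each of the 19 other residues in
every covering tile, so its denominator is exactly 19 × (covering tiles):
1 means the region is predicted to bind no matter what occupies the
position, 0 means no substitution can create binding.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is validated under, chosen once:

* 6000 bivalent loci in disjoint 10-kb slots over 6 chromosomes, so planted
  truth is unambiguous; per-locus peaks of the three marks mutually overlap
  around the locus center with jittered edges.
* Dominance mix 0.43/0.33/0.24, survivin colocalization 0.65, dominance
  shift fraction 0.085 — the frequencies the analysis is expected to
  recover.
* Tags are negative binomial (overdispersed, as ChIP-seq counts are), mean
  240 for the dominant mark versus 30 for the others at size 30. This
  separation makes the planted dominant mark recoverable almost surely
  (flip probability ≈ 10⁻³), so recovered dominance frequencies reflect the
  planted multinomial draw rather than tag noise, and noise-only re-draws
  produce well under 1% spurious dominance shifts.
* Expression changes couple to tag changes through a Gaussian copula with
  planted *Spearman* ρ (internally converted to the Pearson correlation
  2·sin(πρ/6) of the latent Gaussian); 40% of genes receive nominal
  p < 0.05.
* The peptide array plants the rule "≥ 3 aromatic side chains (F/Y/W) in
  the tile": intensity = 3000 + 17,000·rule + N(0, 1500²), averaged over
  two simulated replicate spots, which keeps the planted classes cleanly on
  either side of the 10,000 threshold. Default scale is 20 proteins of 600
  residues (~2400 tiles), comparable to a real array of complex subunits
  and large enough for the two-unit net to generalize (held-out accuracy
  ≥ 0.9 across seeds).

What the generator does **not** emulate: mappability and GC bias, peak
width/signal correlation structure, spatially correlated background,
realistic enhancer–gene distance distributions, or label noise on the
array. Passing tests therefore demonstrate correctness of the computations
and recoverability of planted signal — not robustness to every artifact of
real sequencing data.

## Problem sizes and numerics

The validation suite runs the genome-scale recovery at n = 6000 loci over 5
seeds, enrichment calibration over 200 simulated datasets, interval-oracle
equivalence over 100 random 50-kb toy genomes, and classifier training over
10 seeds — sizes chosen so sampling error is well inside the asserted
tolerances (e.g. a binomial standard error of ~0.6 percentage points
against a ±2-point band). Degenerate inputs are handled explicitly: empty
peak files, all-zero tag regions, zero-length strata, zero shuffle
variance, single-class training labels, and proteins shorter than one tile
all either produce defined results or fail with informative errors, as
exercised in the tests.

## A small worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_bvcr = 600, n_decoys_per_mark = 60,
                    n_decoy_survivin = 60)
ls1 <- simulate_peak_landscape(cfg, seed = 7)
bv <- call_bvcr(ls1$peaks$H3K4me3, ls1$peaks$H3K27me3, ls1$peaks$H3K27ac,
                survivin = ls1$peaks$survivin)
length(bv)                       # 600 regions, no decoy ever qualifies
table(bv$dominant)               # ~43/33/24 mix
mean(bv$survivin_positive)       # ~0.65
dominance_frequency_table(bv)    # chi-square homogeneity across S+/S-
```
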