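---
title: "Methods: quantifying monocyte-derived cell infiltration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying monocyte-derived cell infiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcquant)
```

# Overview

`mdcquant` implements the quantitative chain by which a CD163-positive,
monocyte-derived cell (MDC) population can be identified and measured in
post-mortem brain tissue: relative qPCR quantification, gene-set scoring,
unsupervised two-cluster subject classification, APOE allele calling,
percent-area image quantification with perivascular spatial gradients, and
the nonparametric statistics connecting them. This vignette documents the
models, the parameters that matter, the numerical conventions, and what the
synthetic-data validation does and does not establish.

# Expression quantification

## The 2^-ddCt model

Relative qPCR quantification assumes a doubling of product per cycle, so a
difference of one cycle threshold (Ct) corresponds to a two-fold difference
in template. `ddct_quantify()` subtracts the housekeeper Ct per sample
(input normalization), then the reference-group mean per gene (biological
baseline), and exponentiates:

$$e_{gj} = 2^{-\left[(Ct_{gj} - H_j) -
  \overline{(Ct_g - H)}^{\mathrm{ref}}\right]}.$$

Two consequences worth keeping in mind:

* amplification efficiency is assumed to be exactly 2 per cycle for every
  assay; no efficiency correction is applied;
* the *geometric* mean of reference-group fold changes is exactly 1 per
  gene (the arithmetic mean of reference ddCt values is 0 by construction).
  This identity is asserted to 1e-9 relative tolerance in the tests.

For multi-housekeeper panels, "normalize by the geometric mean of the four
housekeeping genes" is computed as the *arithmetic mean of the four Ct
values*: since expression is `2^-Ct`, the arithmetic mean on the log scale
is precisely the geometric mean on the linear scale. The tests verify this
equivalence against an oracle that works entirely on the linear scale.

Expression stays on the fold-change scale (never log) unless `log2 = TRUE`
is requested; downstream set-scores operate on the fold-change values.

## Gene-set score

For a panel of $n_g$ genes over $n_s$ samples,
$c_{ij} = e_{ij} - \tfrac{1}{n_s}\sum_j e_{ij}$ and
$S_j = \tfrac{1}{n_g}\sum_i c_{ij}$. The score is a per-sample average of
gene-wise mean-centered expression: it sums to zero over the cohort, is
invariant to adding a per-gene constant, and scales linearly with the
expression scale. Because centering is arithmetic (not Z-scoring), genes
with larger fold-change variance contribute more; that is intentional —
the score weights the panel's strongly modulated genes more heavily.

## Clustering and the two-cluster classification

Subjects are clustered on the *Z-scored* panel matrix (per gene across
samples, $n-1$ denominator), while set-scores are computed from the
un-Z-scored expression; the two transforms serve different purposes
(shape-based grouping vs magnitude summary). Clustering uses Manhattan
distances and Ward's linkage in the "ward.D" convention: the
Lance–Williams update applied directly to the raw dissimilarities.
Ward's variance argument assumes squared Euclidean input, so on Manhattan
dissimilarities merge heights are not guaranteed monotone; the package
therefore treats the *merge sequence*, not the height profile, as the
meaningful output. The implementation is `stats::hclust(method =
"ward.D")` behind the package's interface, and the test suite proves the
merge sequence identical to a naive $O(n^3)$ re-scan agglomerator on
hundreds of random instances.

The subject classification cuts the dendrogram at its final merge into two
leaf groups and labels the group with the higher mean CD163-panel
set-score "cluster II". A tie (possible only for degenerate input) is
broken lexicographically, with a warning.

# Synthetic cohort generator

`simulate_cohort()` draws a Braak-stratified cohort whose default sizes
(8 / 26 / 15 / 44 for Braak 0 / II / III–IV / V–VI) match a typical frozen
autopsy collection. Its model:

* Ct of gene $g$ in subject $j$ = deterministic gene baseline + subject
  random effect $u_j \sim N(0, 0.8^2)$ (shared by all genes, emulating
  input-amount variation; it cancels under housekeeper normalization) +
  panel shift + technical noise $N(0, 0.5^2)$. Gaussian Ct noise is the
  standard qPCR assumption.
* Dementia is deterministic from Braak group (V–VI = demented).
* A latent cluster-II label is drawn per subject: probability 0.70 for
  demented, 0.19 for non-demented subjects.
* Cluster-II subjects have the CD163/MDC panels shifted by −2.5 Ct
  (≈ 5.7-fold up), endothelial, chemokine and T-cell markers by −1.5 Ct,
  and the neuronal PV/SOM markers by +1.0 Ct (down-regulation); Braak V–VI
  subjects additionally lose homeostatic-microglia expression (+1.0 Ct)
  regardless of cluster.

The shift magnitudes were fixed once, from the observation that the kind
of cohort this emulates shows order-of-magnitude expression differences
between high- and low-infiltration subjects (cluster separation p-values
of 1e-20 scale and multi-fold violin-plot separations); 2.5 Ct against a
residual noise SD of ≈ 0.56 Ct after normalization yields clearly — but
not artificially perfectly — separated clusters. Housekeeping genes
receive only $u_j$ and technical noise, and the tests verify they are
uncorrelated with the latent label.

What the generator does **not** emulate: amplification-efficiency
differences between assays, missing wells, batch/card effects, RNA
degradation gradients with post-mortem delay, or correlated gene modules
beyond the planted block structure. Passing the recovery tests therefore
shows the pipeline recovers the planted structure under its own model
assumptions — not that it would be equally powerful on real tissue data.

# Image analysis

## Geometry and calibration

Pixel grids are addressed row-major with pixel centers at half-integer
offsets; physical units are converted by `calibrate()`
(pixels-per-micron = scale-bar pixel span / micron span; the standard
slide-scanner bar of 200 µm = 117 px gives 0.585 px/µm). Vessels are
modeled as capsules (thick segments); "distance to a vessel" always means
distance to the capsule *boundary*, zero inside.

## Thresholding and loading

DAB reaction product is dark, so stained pixels are those at or below an
intensity cut (`threshold_spec()`, default cut 175 in the 170–180 range;
155 in 150–160 for the OC amyloid channel). A manual per-image threshold
within a range is not reproducible, so the cut is a single deterministic
parameter. Loading is an exact integer-count percentage, and aggregation
across a subject's images sums labeled and reference counts before
dividing (images with more tissue weigh more). Lowering the cut can only
remove labeled pixels, so loading is monotone in the cut — asserted as a
property test.

## Perivascular halos

`vessel_distance_rings()` computes the Euclidean distance transform from
a vessel mask (via `EBImage::distmap`) and bins pixels into three 85-µm
rings (85/170/255 µm), vessel pixels excluded, boundary pixels assigned
to the inner ring. The rings partition the 255-µm neighbourhood exactly —
also a property test. With several vessels per field, halos overlap;
`halo_table()` resolves overlap by nearest-vessel assignment (computed
analytically from the capsule geometry in synthetic scenes), and vessels
with an empty ring are dropped — with a report — before the Friedman
test, which requires complete blocks. Ring widths are equal (85 µm), so
ring *areas* differ; per-ring loadings normalize the area away.

## Periplaque phenotypes

DAPI-positive cells within a fixed radius of a plaque boundary (closed
boundary: a cell exactly at the radius counts) are classified as
microglia (Iba1+/Trem2+/Cd163−), microglia-like (Iba1+/Trem2+/Cd163+),
infiltrate (Cd163+/Iba1−/Trem2−) or other. The counting radius is not a
published constant; the default of 50 µm (a few soma diameters) is a
documented package choice.

## Synthetic scenes

`simulate_staining_image()` renders dark cells (filled discs, soma radius
3–6 µm) and plaque blobs on a bright background (default 220) with
additive Gaussian noise clipped to [0, 255]. CD163-like cells follow an
inhomogeneous Poisson process with intensity
$\lambda(d) = \lambda_{wall} e^{-d/\ell} + \lambda_{bg}$ in cells/mm²
($d$ = distance to the nearest vessel boundary), simulated by thinning a
homogeneous process at $\lambda_{wall} + \lambda_{bg}$; Iba1-like
microglia are homogeneous. The exponential-decay placement is a modeling
choice — the real spatial law of infiltrating cells is unknown; what is
asserted is only the qualitative structure (density highest at the wall,
decaying with distance). The default decay length of 60 µm places most
perivascular cells inside the first 85-µm halo without emptying the
second. Ground truth records exact coordinates, marker sets, continuous
vessel distances, the vessel mask and the exact painted-pixel fraction
per channel, so threshold-based loading can be checked against truth
exactly (noise-free) or to 0.5 percentage points (noise SD 8: with the
cut 45 intensity units below background, per-pixel misclassification is
a ≈ 5.6σ event and in practice never occurs).

Scenes are grayscale per channel — no RGB DAB/hematoxylin rendering, no
optics/PSF, no 3-D stacks; morphological processes on cells are omitted
as cosmetic. These simplifications do not touch the quantification code
paths being validated.

# Nonparametric statistics

All tests use mid-ranks for ties and report two-sided p-values.

* **Mann–Whitney U**: exact p by the full null distribution of U when
  $n_x + n_y \le 12$ and the data are tie-free; otherwise a normal
  approximation with tie correction and (default) continuity correction.
* **Kruskal–Wallis** and **Friedman** use the standard tie-corrected
  chi-square forms.
* **Dunn's post hoc** follows the pooled-rank z formula with the
  $\sum(t^3 - t)$ tie term after Kruskal–Wallis, and within-block mean
  ranks with denominator $\sqrt{k(k+1)/(6n)}$ after Friedman. P-values
  are unadjusted by default — mirroring the common practice of reporting
  unadjusted Dunn p-values — with a Bonferroni option.
* **Spearman**: Pearson correlation of mid-ranks; exact p by full
  permutation enumeration for $n \le 8$ tie-free, else the t
  approximation.
* **Fisher exact**: two-sided p sums hypergeometric masses not exceeding
  the observed table's (the "mass" rule; a tail-doubling rule is
  available), and both the sample cross-product odds ratio and the
  conditional-MLE odds ratio with an exact (Cornfield-type) CI are
  reported, because the two OR conventions can differ noticeably in
  small tables. Root-finding for the cMLE and CI runs on the log-odds
  scale over [−50, 50] with `uniroot` at 1e-10 tolerance; support
  endpoints yield 0/∞ with one-sided intervals.
* **Chi-square**: Pearson form, warning when any expected count is
  below 5.

Validation is two-route throughout: enumeration oracles (combinatorial
labelings, permutations, hypergeometric sums) and the base-R reference
implementations are both compared against the package's own code.
The null-uniformity checks simulate at sizes in the asymptotic regime the
approximations target (50 + 50 for Mann–Whitney, three groups of 100 for
Kruskal–Wallis/Dunn, 100 blocks × 4 treatments for Friedman): at small
sizes a Kolmogorov–Smirnov test on 2000 null p-values detects the
chi-square approximation's well-known finite-sample error, which is a
property of the approximation, not of an implementation.

# APOE calling

Haplotypes across rs429358/rs7412 map as (T,C) → ε3, (T,T) → ε2,
(C,C) → ε4. The remaining (C,T) haplotype is population-rare; it is
reported as ε1 with `rare_haplotype = TRUE` rather than forced into a
common allele. The doubly heterozygous genotype is compatible with
ε2/ε4 and ε1/ε3 and is resolved to ε2/ε4 (the far more frequent
configuration) with `ambiguous = TRUE`. All nine unordered genotype
combinations are covered by the test suite.

# Pipeline

`run_full()` executes: simulate → normalize (four housekeepers, Braak II
reference) → per-gene Braak screen (Spearman trend + Braak II vs V–VI
Mann–Whitney at α, uncorrected by default to mirror per-gene screening
practice, BH available) → Z-score + cluster screen-positive genes → panel
set-scores with Kruskal–Wallis/Dunn → CD163-panel subject classification
→ chi-square (cluster × Braak) and Fisher (cluster × dementia, oriented
so the odds ratio is cluster-II odds of dementia) → cluster-II vs -I
Mann–Whitney on CCL2, CCR2, CD3E, the endothelial set-score, PV and SOM →
image arm (binarize, loadings, vessel enrichment at 50 µm proximity,
halo gradient with Friedman + Dunn). One seed drives every stage;
`write_report()` stores all tables as TSV plus a JSON manifest, and the
test suite asserts byte-identical reports across repeated runs and that
reported statistics are recomputable from the stored tables.

The gene screen's selection is monotone in α (a larger α never removes a
gene) — asserted as a property test.

# Problem sizes and runtime choices

The validation suite runs entirely on synthetic data generated at test
time: cohorts of 93 subjects (100 independent seeds for the recovery
rate), gradient scenes of 1200 × 900 px with 22 vessels (50 replicates),
a fixed 380 × 380 px vascular template with 200 uniform-stain replicates
for the Friedman type-I rate, 2000-replicate null simulations per test,
and 200–500 random instances for the enumeration-oracle sweeps. These
sizes give binomial standard errors comfortably below the asserted
margins while keeping the full suite in the minutes range on one core.

# Known limitations

* The 2-per-cycle amplification assumption is untested against dilution
  series; efficiency-corrected models are out of scope.
* Ward linkage on Manhattan dissimilarities is a pragmatic convention,
  not a variance-minimizing method; height non-monotonicity can occur.
* The two-cluster cut assumes the cohort's dominant structure is the
  planted low/high dichotomy; with more complex structure the final-merge
  cut may not be the relevant partition.
* Image analyses operate on 2-D sections; periplaque counting on label
  masks ignores 3-D colocalization.
* The synthetic scene's exponential perivascular law and the periplaque
  50-µm radius are modeling choices, flagged as such above.
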