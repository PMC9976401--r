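# mdcquant

Quantification of monocyte-derived cell (MDC) infiltration in post-mortem
brain tissue.

In Alzheimer's disease (AD) hippocampus, a subpopulation of CD163-positive
myeloid cells — negative for the canonical microglial markers Iba1, Tmem119
and Trem2 — appears in the parenchyma of a subset of patients, concentrated
near blood vessels. Demonstrating that these are infiltrating blood
monocytes rather than reactive microglia rests on a chain of quantitative
analyses: relative qPCR quantification of myeloid marker panels across
Braak stages, a per-sample gene-set score, an unsupervised two-cluster
classification of subjects by CD163-panel expression, nonparametric
association tests against neuropathology and dementia, percent-area
("loading") quantification of immunostained sections, and a concentric-halo
analysis of cell density as a function of distance from vessel walls.

`mdcquant` implements that analysis chain as tested, reusable R functions,
together with a synthetic-data generator that produces Ct tables, APOE
genotypes and stained-section images with known ground truth, so every
stage — and the pipeline end to end — can be validated without access to
human tissue data.

## The core quantities

**Relative expression (2^-ddCt).** For target gene *g* in sample *j*, with
housekeeper Ct *H<sub>j</sub>* (one gene, or the arithmetic mean of four
housekeeper Cts — the geometric mean on the linear scale) and a reference
sample group:

> dCt<sub>gj</sub> = Ct<sub>gj</sub> − H<sub>j</sub>,&nbsp;&nbsp;
> ddCt<sub>gj</sub> = dCt<sub>gj</sub> − mean<sub>ref</sub>(dCt<sub>g</sub>),&nbsp;&nbsp;
> e<sub>gj</sub> = 2^(−ddCt<sub>gj</sub>)

**Gene-set score.** For a marker panel of n<sub>g</sub> genes over
n<sub>s</sub> samples, c<sub>ij</sub> = e<sub>ij</sub> −
(1/n<sub>s</sub>) Σ<sub>j</sub> e<sub>ij</sub> and S<sub>j</sub> =
(1/n<sub>g</sub>) Σ<sub>i</sub> c<sub>ij</sub>; scores sum to zero over the
cohort, and S<sub>j</sub> > 0 marks above-average panel expression.

**Subject classification.** Samples are clustered on the Z-scored CD163
panel with Ward's linkage on Manhattan distances (the Lance–Williams
ward.D update applied to the raw dissimilarities); cutting the dendrogram
at its last merge gives two groups, and the one with the higher mean
gene-set score is "cluster II" (high CD163 expression).

**Loading.** Percent of reference tissue area covered by stain:
100 × Σ labeled px / Σ reference px, with dark-on-bright (DAB) polarity
and a deterministic intensity cut (default 175 within the 170–180 range;
155 for the OC amyloid channel). Aggregation across a subject's images
sums counts before dividing.

**Perivascular halos.** The Euclidean distance transform from the vessel
boundary defines three concentric rings of 85 µm width (85/170/255 µm);
per-vessel ring loadings form matched blocks for a Friedman test of the
spatial gradient, with Dunn's post hoc comparisons.

The nonparametric battery (Mann–Whitney U with exact small-sample branch,
Kruskal–Wallis, Friedman, Dunn, Spearman, Fisher exact with conditional-MLE
odds ratio, chi-square) is implemented in the package and verified against
enumeration oracles and the base-R reference implementations.

## Worked example

Simulate a Braak-stratified cohort of 93 subjects with a planted
CD163-high subpopulation (70 % of demented, 19 % of non-demented
subjects), quantify, score, classify and test:

```r
library(mdcquant)

sim   <- simulate_cohort(cohort_config(seed = 11))
e     <- multi_housekeeper_normalize(sim$ct)           # 2^-ddCt, 4 housekeepers
panel <- default_gene_panels()$cd163_cluster           # CD163 IFITM3 CCR2 CD68 MSR1
score <- gene_set_score(e, panel)
tree  <- agglomerative_cluster(t(zscore_genes(e[panel, ])))
cl    <- classify_two_clusters(tree, score)
cl
#> cluster_assignment: 44 cluster-I, 49 cluster-II samples

dem <- factor(sim$metadata$demented, labels = c("non-demented", "demented"))
table(cluster = cl$labels, dementia = dem)
#>        dementia
#> cluster non-demented demented
#>      I            36        8
#>      II           13       36

fisher_exact(table(cl$labels, dem)[c("II", "I"), c("demented", "non-demented")])
#> Fisher exact
#>   statistic = 6.50563e-08  p = 1.0095e-07

kruskal_wallis(split(score$scores, sim$ct$group))
#> Kruskal-Wallis
#>   statistic = 17.16928  p = 0.00065229
```

The classification recovers the planted subpopulation (here with a
conditional-MLE odds ratio of 12.0, 95 % CI 4.2–38.5, for cluster II being
demented), and the CD163 set-score rises with Braak stage. The image arm
is exercised the same way from `scene_config()` /
`simulate_staining_image()`, and `run_full(run_config(seed = 7))` runs
every stage on one seed and returns a structured report
(`write_report()` writes TSV tables plus a JSON manifest).

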