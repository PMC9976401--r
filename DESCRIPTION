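Package: mdcquant
Title: Quantification of Monocyte-Derived Cell Infiltration in Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular and histological quantification of
    monocyte-derived cell (MDC) infiltration in post-mortem brain tissue.
    Implements comparative 2^-ddCt qPCR quantification with single- or
    multi-housekeeper normalization, per-sample gene-set scores, Ward-linkage
    hierarchical clustering on Manhattan distances with a two-cluster subject
    classification, APOE epsilon-allele calling from rs429358/rs7412
    genotypes, threshold-based percent-area ("loading") image quantification,
    perivascular concentric-halo spatial gradient analysis, periplaque
    phenotype counting, and the nonparametric test battery these analyses
    rely on (Mann-Whitney, Kruskal-Wallis, Friedman, Dunn post hoc, Spearman,
    chi-square, Fisher exact). A synthetic-data generator produces Ct tables,
    genotypes and stained-section images with known ground truth so the full
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
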