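#' Comparative 2^-ddCt expression quantification
#'
#' Converts raw cycle thresholds into fold-change expression relative to a
#' housekeeper signal and a reference sample group, the standard comparative
#' double-delta-Ct method of relative qPCR quantification.
#'
#' For each target gene g and sample j,
#' \deqn{\Delta Ct_{gj} = Ct_{gj} - H_j,}
#' where `H_j` is the housekeeper Ct of sample j (a single gene, or the
#' arithmetic mean of several housekeeper Cts, which equals the geometric
#' mean of their expression on the linear 2^-Ct scale);
#' \deqn{\Delta\Delta Ct_{gj} = \Delta Ct_{gj} - \overline{\Delta Ct_g}^{ref},}
#' the reference being the mean over the reference-group samples; and the
#' reported expression is \eqn{e_{gj} = 2^{-\Delta\Delta Ct_{gj}}}.
#'
#' Samples missing a housekeeper Ct are dropped with a message. By
#' construction the *arithmetic* mean of the reference-group ddCt values is
#' zero per gene, i.e. the *geometric* mean of reference-group fold-changes
#' is 1.
#'
#' @param ct A [ct_table()].
#' @param housekeepers Character vector of one or more housekeeping genes to
#'   normalize by; defaults to the table's designated housekeeping set.
#' @param log2 If `TRUE` return log2 fold-change (`-ddCt`) instead of the
#'   linear `2^-ddCt` scale.
#'
#' @return Numeric matrix of expression values, genes in rows and samples in
#'   columns (only target genes; housekeepers are consumed by the
#'   normalization).
#' @export
ddct_quantify <- function(ct, housekeepers = ct$housekeeping, log2 = FALSE) {
  stopifnot(inherits(ct, "ct_table"))
  housekeepers <- as.character(housekeepers)
  if (!length(housekeepers))
    stop("at least one housekeeping gene is required")
  missing_hk <- setdiff(housekeepers, colnames(ct$ct))
  if (length(missing_hk))
    stop("housekeeper(s) not in table: ", paste(missing_hk, collapse = ", "))
  targets <- setdiff(colnames(ct$ct), housekeepers)
  if (!length(targets)) stop("no target genes left after removing housekeepers")

  hk <- ct$ct[, housekeepers, drop = FALSE]
  bad <- rowSums(!is.finite(hk)) > 0
  keep <- rownames(ct$ct)
  if (any(bad)) {
    message("dropping ", sum(bad), " sample(s) with missing housekeeper Ct: ",
            paste(keep[bad], collapse = ", "))
    keep <- keep[!bad]
  }
  ref <- intersect(ct$reference_samples, keep)
  if (!length(ref)) stop("reference group is empty after sample filtering")

  h <- rowMeans(hk[keep, , drop = FALSE])            # H_j per sample
  dct <- t(ct$ct[keep, targets, drop = FALSE] - h)   # genes x samples
  ref_mean <- rowMeans(dct[, ref, drop = FALSE])
  ddct <- dct - ref_mean
  if (log2) -ddct else 2^(-ddct)
}

#' Multi-housekeeper ddCt normalization
#'
#' ddCt quantification normalized against the geometric mean of four
#' housekeeping genes, the convention of array microfluidic-card qPCR
#' panels. On the Ct (log2) scale the geometric mean of expression is the
#' arithmetic mean of the Ct values, so `H_j` is the mean of the four
#' housekeeper Cts; the reference group is the table's designated reference
#' (typically the Braak II group).
#'
#' @param ct A [ct_table()].
#' @param housekeepers Exactly four housekeeping genes; defaults to the
#'   table's designated housekeeping set.
#' @inheritParams ddct_quantify
#' @return Numeric matrix of fold-change expression, genes x samples.
#' @export
multi_housekeeper_normalize <- function(ct, housekeepers = ct$housekeeping,
                                        log2 = FALSE) {
  housekeepers <- as.character(housekeepers)
  if (length(housekeepers) != 4)
    stop("multi_housekeeper_normalize expects exactly four housekeeping genes, got ",
         length(housekeepers))
  ddct_quantify(ct, housekeepers = housekeepers, log2 = log2)
}

#' Per-gene Z-score normalization
#'
#' Standardizes each gene (row) across samples to mean 0 and unit sample
#' standard deviation (n - 1 denominator), the transform applied before
#' heatmap display and hierarchical clustering.
#'
#' @param e Numeric matrix, genes in rows and samples in columns.
#' @return Matrix of the same shape with each row standardized.
#' @export
zscore_genes <- function(e) {
  if (!is.matrix(e) || !is.numeric(e)) stop("`e` must be a numeric matrix")
  if (ncol(e) < 2) stop("need at least two samples to Z-score")
  sds <- apply(e, 1, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(rownames(e)[zero], collapse = ", "))
  (e - rowMeans(e)) / sds
}

#' Gene-set score
#'
#' Per-sample scalar summary of a gene panel: the expression matrix is
#' centered gene-wise, \eqn{c_{ij} = e_{ij} - \frac{1}{n_s}\sum_j e_{ij}},
#' and the score of sample j is the panel average
#' \eqn{S_j = \frac{1}{n_g}\sum_i c_{ij}}. Scores sum to zero over samples
#' by construction; positive scores mark samples expressing the panel above
#' the cohort average.
#'
#' @param e Numeric matrix of normalized expression, genes x samples.
#' @param panel Character vector of panel gene names (must all be rows of
#'   `e`).
#' @return An object of class `gene_set_score`: list with `panel`, `scores`
#'   (named per-sample numeric) and `centered` (the c_ij matrix, retained
#'   for audit).
#' @export
gene_set_score <- function(e, panel) {
  if (!is.matrix(e) || !is.numeric(e)) stop("`e` must be a numeric matrix")
  if (ncol(e) < 2) stop("gene-set score needs at least two samples")
  panel <- as.character(panel)
  if (!length(panel)) stop("panel is empty")
  missing <- setdiff(panel, rownames(e))
  if (length(missing))
    stop("panel gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- e[panel, , drop = FALSE]
  centered <- sub - rowMeans(sub)
  scores <- colMeans(centered)
  structure(list(panel = panel, scores = scores, centered = centered),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat("gene_set_score over", length(x$panel), "genes,",
      length(x$scores), "samples\n")
  print(summary(unname(x$scores)))
  invisible(x)
}
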