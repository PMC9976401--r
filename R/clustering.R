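#' Agglomerative clustering with Ward linkage on Manhattan distances
#'
#' Hierarchical agglomeration of the rows of `x` using pairwise Manhattan
#' (city-block) dissimilarities and the Lance--Williams Ward update applied
#' directly to those dissimilarities,
#' \deqn{d(k, i \cup j) = \frac{(n_i + n_k) d_{ik} + (n_j + n_k) d_{jk}
#'       - n_k d_{ij}}{n_i + n_j + n_k},}
#' i.e. the "ward.D on a precomputed distance" convention. Because the
#' Ward variance interpretation assumes squared Euclidean input, merge
#' heights on Manhattan dissimilarities are not guaranteed monotone; the
#' merge *sequence* is what downstream classification consumes.
#'
#' @param x Numeric matrix; rows are the items being clustered (samples or
#'   genes), columns the features. Row names identify items.
#' @param metric Dissimilarity; only `"manhattan"` is supported.
#' @param linkage Linkage; only `"ward"` (ward.D convention) is supported.
#' @return An object of class `merge_tree`: list with `hclust` (the
#'   underlying [stats::hclust] object), `labels`, and `merges`, a list of
#'   merge records `(members_a, members_b, height)` in agglomeration order,
#'   each member set sorted by label.
#' @export
agglomerative_cluster <- function(x, metric = "manhattan", linkage = "ward") {
  metric <- match.arg(metric, "manhattan")
  linkage <- match.arg(linkage, "ward")
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (nrow(x) < 2) stop("need at least two items to cluster")
  if (any(is.na(x))) stop("NA/NaN in clustering input")
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  d <- stats::dist(x, method = "manhattan")
  hc <- stats::hclust(d, method = "ward.D")
  structure(
    list(hclust = hc, labels = hc$labels, merges = merge_records(hc)),
    class = "merge_tree"
  )
}

# Expand an hclust merge matrix into explicit member sets per merge step.
merge_records <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  leaf <- function(i) hc$labels[i]
  get_members <- function(code) {
    if (code < 0) leaf(-code) else members[[code]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- sort(get_members(hc$merge[s, 1]))
    b <- sort(get_members(hc$merge[s, 2]))
    members[[s]] <- sort(c(a, b))
    out[[s]] <- list(members_a = a, members_b = b, height = hc$height[s])
  }
  out
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("merge_tree over", length(x$labels), "items (",
      length(x$merges), "merges; Ward linkage, Manhattan distance)\n")
  invisible(x)
}

#' Two-cluster subject classification
#'
#' Cuts the dendrogram at its final merge into two leaf groups and labels
#' the group with the higher mean gene-set score "II" (high expression) and
#' the other "I". This reproduces the data-driven low/high classification
#' used to split a cohort on a marker panel.
#'
#' @param tree A `merge_tree` from [agglomerative_cluster()] over samples.
#' @param score A [gene_set_score()] over the same samples.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named factor with levels I, II), `label_rule` (which leaf group got
#'   "II" and the group mean scores) and `tree`.
#' @details On a tie in mean scores (degenerate input) the leaf group
#'   containing the lexicographically first sample name is labeled "I",
#'   with a warning.
#' @export
classify_two_clusters <- function(tree, score) {
  stopifnot(inherits(tree, "merge_tree"), inherits(score, "gene_set_score"))
  samples <- tree$labels
  if (!setequal(samples, names(score$scores)))
    stop("tree and score cover different samples")
  cut <- stats::cutree(tree$hclust, k = 2)
  m1 <- mean(score$scores[names(cut)[cut == 1]])
  m2 <- mean(score$scores[names(cut)[cut == 2]])
  if (isTRUE(all.equal(m1, m2))) {
    warning("tie in mean gene-set scores; applying lexicographic tie-break")
    first <- min(samples)
    low_group <- cut[[first]]
  } else {
    low_group <- if (m1 < m2) 1L else 2L
  }
  labels <- factor(ifelse(cut == low_group, "I", "II"), levels = c("I", "II"))
  names(labels) <- names(cut)
  structure(
    list(labels = labels,
         label_rule = list(group_means = c(m1, m2),
                           high_group = setdiff(1:2, low_group)),
         tree = tree),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", sum(x$labels == "I"), "cluster-I,",
      sum(x$labels == "II"), "cluster-II samples\n")
  invisible(x)
}
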