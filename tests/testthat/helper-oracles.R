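# Independent oracles used across the test files. These deliberately use
# naive step-by-step formulations (or base R's reference implementations)
# so that they share no code path with the package.

# step-by-step ddCt: single- or multi-housekeeper, explicit loops
oracle_ddct <- function(ct_mat, housekeepers, ref_samples) {
  targets <- setdiff(colnames(ct_mat), housekeepers)
  out <- matrix(NA_real_, length(targets), nrow(ct_mat),
                dimnames = list(targets, rownames(ct_mat)))
  h <- numeric(nrow(ct_mat))
  for (j in seq_len(nrow(ct_mat)))
    h[j] <- mean(ct_mat[j, housekeepers])
  for (g in targets) {
    dct <- ct_mat[, g] - h
    ref_mean <- mean(dct[ref_samples])
    for (j in seq_len(nrow(ct_mat)))
      out[g, rownames(ct_mat)[j]] <- 2^(-(dct[j] - ref_mean))
  }
  out
}

# multi-housekeeper normalization on the linear scale: expression 2^-Ct,
# geometric mean of housekeepers, ratio to the reference-group geometric
# mean of the normalized expression
oracle_linear_geomean <- function(ct_mat, housekeepers, ref_samples) {
  targets <- setdiff(colnames(ct_mat), housekeepers)
  lin <- 2^(-ct_mat)
  geo_hk <- apply(lin[, housekeepers, drop = FALSE], 1,
                  function(v) exp(mean(log(v))))
  norm <- lin[, targets, drop = FALSE] / geo_hk
  ref_geo <- apply(norm[ref_samples, , drop = FALSE], 2,
                   function(v) exp(mean(log(v))))
  t(t(norm) / ref_geo)
}

# centering-then-averaging gene-set score
oracle_set_score <- function(e, panel) {
  c_ij <- e[panel, , drop = FALSE]
  for (i in seq_len(nrow(c_ij)))
    c_ij[i, ] <- c_ij[i, ] - mean(c_ij[i, ])
  apply(c_ij, 2, mean)
}

# naive O(n^3) agglomeration: full re-scan of the active dissimilarity
# matrix at every step, Lance-Williams ward.D update on Manhattan input,
# ties broken by smallest (i, j) scan order
oracle_ward_manhattan <- function(x) {
  n <- nrow(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  D <- as.matrix(stats::dist(x, method = "manhattan"))
  members <- as.list(labels)
  sizes <- rep(1, n)
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (ai in seq_along(active)) {
      for (aj in seq_along(active)) {
        if (aj <= ai) next
        i <- active[ai]; j <- active[aj]
        if (D[i, j] < bestd - 1e-12) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- list(
      members_a = sort(members[[i]]), members_b = sort(members[[j]]),
      height = bestd)
    # ward.D Lance-Williams update against every other active cluster
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        ((sizes[i] + sizes[k]) * D[i, k] + (sizes[j] + sizes[k]) * D[j, k] -
           sizes[k] * D[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  merges
}

# compare two merge-record lists step by step (unordered pair of member
# sets, heights to tolerance)
expect_same_merges <- function(merges, oracle, tol = 1e-8) {
  expect_equal(length(merges), length(oracle))
  for (s in seq_along(merges)) {
    got <- list(sort(merges[[s]]$members_a), sort(merges[[s]]$members_b))
    want <- list(sort(oracle[[s]]$members_a), sort(oracle[[s]]$members_b))
    ok <- (identical(got[[1]], want[[1]]) && identical(got[[2]], want[[2]])) ||
          (identical(got[[1]], want[[2]]) && identical(got[[2]], want[[1]]))
    expect_true(ok, label = sprintf("merge step %d pair", s))
    expect_equal(merges[[s]]$height, oracle[[s]]$height, tolerance = tol)
  }
}

# exact two-sided Mann-Whitney p by enumeration of all C(N, nx) labelings
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  mn <- nx * ny
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mn / 2) >= abs(u_obs - mn / 2) - 1e-9)
}

# small cohort-arm pipeline: simulate, normalize, score, cluster, classify
classify_cohort <- function(seed, config = NULL) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  config$seed <- as.integer(seed)
  sim <- simulate_cohort(config)
  e <- multi_housekeeper_normalize(sim$ct)
  panel <- config$gene_panels$cd163_cluster
  sc <- gene_set_score(e, panel)
  tree <- agglomerative_cluster(t(zscore_genes(e[panel, , drop = FALSE])))
  cl <- classify_two_clusters(tree, sc)
  list(labels = cl$labels, truth = sim$ground_truth$cluster_labels,
       metadata = sim$metadata, e = e, score = sc)
}
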