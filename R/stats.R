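#' @title Nonparametric test battery
#' @description Self-contained implementations of the rank and exact tests
#'   the analysis pipeline relies on. All tests use mid-ranks for ties and
#'   report two-sided p-values; every result is a `test_result` list that
#'   serializes cleanly to JSON.
#' @name nonparam_stats
NULL

test_result <- function(statistic, p_value, method, n,
                        tie_correction = FALSE, degenerate = FALSE,
                        extras = list()) {
  structure(
    list(statistic = unname(statistic),
         p_value = min(1, max(0, unname(p_value))),
         method = method, n = n,
         tie_correction = tie_correction, degenerate = degenerate,
         extras = extras),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  if (x$degenerate) cat("  (degenerate input)\n")
  invisible(x)
}

# sum of (t^3 - t) over tie groups of a pooled vector
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. The U statistic counts, over all cross pairs,
#' how often an `x` value exceeds a `y` value (ties count 1/2). The exact
#' two-sided p-value is computed from the exact null distribution of U when
#' `n_x + n_y <= 12` and the pooled data are tie-free (`mode = "auto"`);
#' otherwise a normal approximation with tie correction and (by default)
#' continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A `test_result` with the U statistic for `x`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                           continuity = TRUE) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (any(!is.finite(pooled))) stop("non-finite values in input")
  n <- nx + ny
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (all(pooled == pooled[1]))
    return(test_result(u, 1, "Mann-Whitney U", c(nx = nx, ny = ny),
                       tie_correction = TRUE, degenerate = TRUE))

  exact <- switch(mode,
    exact = { if (ties) stop("exact Mann-Whitney p undefined with ties"); TRUE },
    asymptotic = FALSE,
    auto = n <= 12 && !ties)

  if (exact) {
    # exact null distribution of U (stats::dwilcox); two-sided p is the
    # probability of a U at least as far from the mean mn/2 as observed
    mn <- nx * ny
    dev <- abs(u - mn / 2)
    ks <- 0:mn
    p <- sum(stats::dwilcox(ks[abs(ks - mn / 2) >= dev - 1e-9], nx, ny))
    return(test_result(u, p, "Mann-Whitney U (exact)",
                       c(nx = nx, ny = ny)))
  }

  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
  if (sigma2 <= 0)
    return(test_result(u, 1, "Mann-Whitney U (normal approximation)",
                       c(nx = nx, ny = ny), tie_correction = ties,
                       degenerate = TRUE))
  dev <- u - mu
  cc <- if (continuity) sign(dev) * 0.5 else 0
  z <- if (abs(dev) <= abs(cc)) 0 else (dev - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(u, p, "Mann-Whitney U (normal approximation)",
              c(nx = nx, ny = ny), tie_correction = ties,
              extras = list(z = z))
}

#' Kruskal-Wallis rank test
#'
#' k-sample extension of the rank-sum test with the standard tie
#' correction; p-value from the chi-square approximation with k - 1 df.
#'
#' @param groups A list of two or more numeric samples (each with at least
#'   two observations).
#' @return A `test_result` with the tie-corrected H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of at least two samples")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs at least two observations")
  pooled <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(pooled))) stop("non-finite values in input")
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  h <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  corr <- 1 - tie_term(r) / (N^3 - N)
  if (corr <= 0)
    return(test_result(0, 1, "Kruskal-Wallis", sizes,
                       tie_correction = TRUE, degenerate = TRUE))
  h <- h / corr
  df <- length(groups) - 1
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  test_result(h, p, "Kruskal-Wallis", sizes,
              tie_correction = anyDuplicated(pooled) > 0,
              extras = list(df = df))
}

#' Friedman rank test for matched data
#'
#' Repeated-measures rank test: observations are ranked within each block
#' (mid-ranks on ties), and the tie-corrected Friedman chi-square is
#' referred to a chi-square distribution with k - 1 df. Incomplete blocks
#' are rejected; callers quantifying per-vessel ring loadings should drop
#' vessels with an empty ring before testing.
#'
#' @param block_matrix Numeric matrix, blocks in rows and treatments in
#'   columns, no missing cells.
#' @return A `test_result`.
#' @export
friedman <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m)) stop("`block_matrix` must be numeric")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least two blocks and two treatments")
  if (any(is.na(m)))
    stop("incomplete blocks: remove blocks with missing cells before testing")
  n <- nrow(m); k <- ncol(m)
  rk <- t(apply(m, 1, rank))
  R <- colSums(rk)
  num <- (k - 1) * sum((R - n * (k + 1) / 2)^2)
  den <- sum(rk^2) - n * k * (k + 1)^2 / 4
  if (den <= 0)
    return(test_result(0, 1, "Friedman", c(blocks = n, treatments = k),
                       tie_correction = TRUE, degenerate = TRUE))
  chisq <- num / den
  p <- stats::pchisq(chisq, k - 1, lower.tail = FALSE)
  test_result(chisq, p, "Friedman", c(blocks = n, treatments = k),
              tie_correction = any(apply(m, 1, anyDuplicated) > 0),
              extras = list(df = k - 1))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis test (pooled
#' ranks with tie correction) or a Friedman test (within-block ranks).
#' For the Kruskal-Wallis parent,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}};}
#' for the Friedman parent the denominator is \eqn{\sqrt{k(k+1)/(6n)}} on
#' mean within-block ranks. P-values are two-sided and unadjusted by
#' default.
#'
#' @param groups For `parent = "kw"`, a named list of numeric samples; for
#'   `parent = "friedman"`, a blocks x treatments matrix.
#' @param parent `"kw"` or `"friedman"`.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_pairwise <- function(groups, parent = c("kw", "friedman"),
                          adjust = c("none", "bonferroni")) {
  parent <- match.arg(parent)
  adjust <- match.arg(adjust)
  if (parent == "kw") {
    if (!is.list(groups) || length(groups) < 2)
      stop("`groups` must be a list of at least two samples")
    sizes <- lengths(groups)
    if (any(sizes == 0)) {
      message("dropping empty group(s)")
      groups <- groups[sizes > 0]
      sizes <- lengths(groups)
    }
    nm <- if (is.null(names(groups))) paste0("g", seq_along(groups))
          else names(groups)
    pooled <- unlist(groups, use.names = FALSE)
    N <- length(pooled)
    r <- rank(pooled)
    g <- rep(seq_along(groups), sizes)
    rbar <- tapply(r, g, mean)
    v <- N * (N + 1) / 12 - tie_term(r) / (12 * (N - 1))
    pairs <- utils::combn(seq_along(groups), 2)
    z <- apply(pairs, 2, function(ij) {
      (rbar[ij[1]] - rbar[ij[2]]) /
        sqrt(v * (1 / sizes[ij[1]] + 1 / sizes[ij[2]]))
    })
  } else {
    m <- as.matrix(groups)
    if (nrow(m) < 2 || ncol(m) < 2)
      stop("need at least two blocks and two treatments")
    if (any(is.na(m))) stop("incomplete blocks")
    n <- nrow(m); k <- ncol(m)
    nm <- if (is.null(colnames(m))) paste0("t", seq_len(k)) else colnames(m)
    rbar <- colMeans(t(apply(m, 1, rank)))
    pairs <- utils::combn(seq_len(k), 2)
    z <- apply(pairs, 2, function(ij) {
      (rbar[ij[1]] - rbar[ij[2]]) / sqrt(k * (k + 1) / (6 * n))
    })
  }
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjust == "bonferroni") pmin(1, p * ncol(pairs)) else p
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = unname(z), p_value = unname(p), p_adjusted = unname(p_adj),
             stringsAsFactors = FALSE)
}

# all permutations of 1..n as a matrix (n! rows); n is small (<= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks. The p-value is exact (full
#' permutation enumeration) for `n <= 8` tie-free inputs under
#' `mode = "auto"`, otherwise from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with n - 2 df.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return A `test_result` with rho as the statistic.
#' @export
spearman_corr <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least three observations")
  if (any(!is.finite(c(x, y)))) stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0

  exact <- switch(mode,
    exact = { if (ties) stop("exact Spearman p undefined with ties"); TRUE },
    asymptotic = FALSE,
    auto = n <= 8 && !ties)

  if (exact) {
    perms <- all_perms(n)
    sx <- rx - mean(rx)
    denom <- sum(sx^2)                       # == sum((ry - mean)^2), tie-free
    rho_perm <- (perms[, ] - mean(ry)) %*% sx / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(test_result(rho, p, "Spearman correlation (exact)", n))
  }

  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  test_result(rho, p, "Spearman correlation (t approximation)", n,
              tie_correction = ties)
}

# noncentral hypergeometric log-weights for the 2x2 conditional
# distribution: support k, log w_k = log C(c1, k) + log C(n - c1, r1 - k)
nchg_support <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  list(k = k,
       logw = lchoose(c1, k) + lchoose(n - c1, r1 - k),
       r1 = r1, c1 = c1, n = n)
}

nchg_pmf <- function(sup, log_psi) {
  lp <- sup$logw + sup$k * log_psi
  lp <- lp - max(lp)
  w <- exp(lp)
  w / sum(w)
}

#' Fisher's exact test for 2x2 tables
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's (the "probability
#' mass" rule; a tail-doubling rule is available). Reports both the sample
#' cross-product odds ratio and the conditional maximum-likelihood odds
#' ratio with an exact (Cornfield) confidence interval.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param p_rule `"mass"` (default) or `"doubling"`.
#' @param conf_level Confidence level of the exact CI (default 0.95).
#' @return A `test_result`; `extras` holds `or_sample`, `or_cmle`,
#'   `or_ci`, and a `zero_cell` flag.
#' @export
fisher_exact <- function(table, p_rule = c("mass", "doubling"),
                         conf_level = 0.95) {
  p_rule <- match.arg(p_rule)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("`table` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(test_result(NA_real_, 1, "Fisher exact", sum(tab),
                       degenerate = TRUE,
                       extras = list(or_sample = NA_real_,
                                     or_cmle = NA_real_,
                                     or_ci = c(NA_real_, NA_real_),
                                     zero_cell = TRUE)))
  a <- tab[1, 1]
  sup <- nchg_support(tab)
  pmf <- nchg_pmf(sup, 0)                      # central: psi = 1
  p_obs <- pmf[sup$k == a]
  p <- switch(p_rule,
    mass = sum(pmf[pmf <= p_obs * (1 + 1e-7)]),
    doubling = min(1, 2 * min(sum(pmf[sup$k <= a]), sum(pmf[sup$k >= a]))))

  zero_cell <- any(tab == 0)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])

  # conditional MLE: psi with E_psi[K] = a; exact CI by inverting tail tests
  kmin <- min(sup$k); kmax <- max(sup$k)
  cond_mean <- function(lp) sum(sup$k * nchg_pmf(sup, lp))
  solve_lp <- function(f, target) {
    stats::uniroot(function(lp) f(lp) - target, c(-50, 50),
                   tol = 1e-10)$root
  }
  or_cmle <- if (a == kmin) 0 else if (a == kmax) Inf else
    exp(solve_lp(cond_mean, a))
  alpha <- 1 - conf_level
  upper_tail <- function(lp) sum(nchg_pmf(sup, lp)[sup$k >= a])
  lower_tail <- function(lp) sum(nchg_pmf(sup, lp)[sup$k <= a])
  ci_lo <- if (a == kmin) 0 else exp(solve_lp(upper_tail, alpha / 2))
  ci_hi <- if (a == kmax) Inf else exp(solve_lp(lower_tail, alpha / 2))

  test_result(p_obs, p, "Fisher exact", sum(tab),
              extras = list(or_sample = or_sample, or_cmle = or_cmle,
                            or_ci = c(ci_lo, ci_hi),
                            conf_level = conf_level,
                            zero_cell = zero_cell))
}

#' Pearson chi-square test of independence
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} over an r x c contingency table with
#' (r-1)(c-1) degrees of freedom; warns when any expected count is below 5.
#'
#' @param table Matrix of non-negative counts with positive margins.
#' @return A `test_result`.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin: drop empty rows/columns before testing")
  E <- outer(rs, cs) / n
  if (any(E < 5))
    warning("expected count below 5; chi-square approximation may be poor")
  chisq <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  test_result(chisq, p, "Pearson chi-square", n, extras = list(df = df))
}

#' Serialize a test result to JSON
#' @param x A `test_result`.
#' @return A JSON string recording method, statistic, p-value and options.
#' @export
test_result_json <- function(x) {
  stopifnot(inherits(x, "test_result"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, null = "null")
}
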