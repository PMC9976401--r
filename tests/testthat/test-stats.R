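test_that("Mann-Whitney exact branch: worked case and enumeration oracle", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  # identical samples are exchangeable
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(100, 5); y <- sample(100, 5) + 0.5
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney asymptotic branch agrees with wilcox.test", {
  set.seed(21)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  r <- mann_whitney_u(x, y, mode = "asymptotic")
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  # with ties
  xt <- round(rnorm(15), 1); yt <- round(rnorm(15, 0.3), 1)
  rt <- mann_whitney_u(xt, yt, mode = "asymptotic")
  wt <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(rt$p_value, wt$p.value, tolerance = 1e-10)
  expect_true(rt$tie_correction)
})

test_that("exact and asymptotic Mann-Whitney branches agree near the switch", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Kruskal-Wallis: identity cases and agreement with kruskal.test", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- kruskal_wallis(g)
  expect_equal(r$p_value, kruskal.test(unlist(g),
                                       rep(1:3, each = 3))$p.value)
  set.seed(12)
  g <- list(rnorm(8), rnorm(10, 1), round(rnorm(9), 1))
  r <- kruskal_wallis(g)
  k <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(r$statistic, unname(k$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, k$p.value, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(rnorm(5))), "two samples")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(14, 0.8)
  h <- kruskal_wallis(list(x, y))$statistic
  z <- mann_whitney_u(x, y, mode = "asymptotic", continuity = FALSE)$extras$z
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("Friedman: perfect concordance, tie-free agreement, sign test", {
  m <- matrix(rep(c(1, 5, 9), each = 10), 10, 3)  # identical rankings
  r <- friedman(m)
  expect_equal(r$statistic, 20)
  expect_equal(r$p_value, pchisq(20, 2, lower.tail = FALSE))
  set.seed(14)
  m <- matrix(rnorm(15 * 4), 15, 4)
  r <- friedman(m)
  f <- friedman.test(m)
  expect_equal(r$statistic, unname(f$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, f$p.value, tolerance = 1e-12)
  # k = 2: direction consistent with the sign of block differences
  m2 <- cbind(rnorm(12), rnorm(12) + 2)
  r2 <- friedman(m2)
  signs <- sum(m2[, 2] > m2[, 1])
  if (signs == 12) expect_lt(r2$p_value, 0.01)
  expect_error(friedman(matrix(c(1, NA, 2, 3), 2, 2)), "ncomplete")
})

test_that("Dunn pairwise: symmetry, Mann-Whitney cross-check, power", {
  # identical groups give z = 0, p = 1
  d <- dunn_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d$z, 0)
  expect_equal(d$p_value, 1)
  # no ties, two groups: Dunn z equals the (uncorrected) MW asymptotic z
  set.seed(15)
  x <- rnorm(10); y <- rnorm(12)
  d <- dunn_pairwise(list(x = x, y = y))
  z <- mann_whitney_u(x, y, mode = "asymptotic", continuity = FALSE)$extras$z
  expect_equal(abs(d$z), abs(z), tolerance = 1e-10)
  # the truly shifted pair attains the smallest p in most seeds
  hits <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
    d <- dunn_pairwise(g)
    shifted <- d$p_value[(d$group1 == "a" & d$group2 == "c")]
    hits <- hits + (shifted <= min(d$p_value) + 1e-15 ||
                      d$p_value[d$group1 == "b" & d$group2 == "c"] ==
                        min(d$p_value))
  }
  expect_gte(hits / 40, 0.95)
  # bonferroni multiplies by the number of pairs
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  d0 <- dunn_pairwise(g)
  db <- dunn_pairwise(g, adjust = "bonferroni")
  expect_equal(db$p_adjusted, pmin(1, d0$p_value * 3))
})

test_that("Dunn after Friedman uses within-block ranks", {
  set.seed(16)
  m <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  m[, 1] <- m[, 1] + 2
  d <- dunn_pairwise(m, parent = "friedman")
  expect_equal(nrow(d), 3)
  expect_lt(d$p_value[d$group1 == "r1" & d$group2 == "r3"], 0.05)
  rbar <- colMeans(t(apply(m, 1, rank)))
  z12 <- (rbar[1] - rbar[2]) / sqrt(3 * 4 / (6 * 20))
  expect_equal(d$z[1], unname(z12), tolerance = 1e-12)
})

test_that("Spearman: monotone identities and exact enumeration", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_corr(x, rank(x))$statistic, 1)
  expect_equal(spearman_corr(x, -x)$statistic, -1)
  set.seed(17)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    r <- spearman_corr(x, y)           # exact branch at n = 6, tie-free
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(r$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_corr(rep(1, 5), rnorm(5)), "constant")
})

test_that("Spearman t approximation agrees with cor.test on larger n", {
  set.seed(18)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  r <- spearman_corr(x, y, mode = "asymptotic")
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-6)
})

test_that("Fisher exact: enumeration cases and fisher.test cross-check", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  set.seed(19)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    r <- fisher_exact(tab)
    f <- fisher.test(tab)
    expect_equal(r$p_value, f$p.value, tolerance = 1e-9)
    expect_equal(r$extras$or_cmle, unname(f$estimate), tolerance = 1e-3)
    # fisher.test inverts the same tail tests with a coarser root tolerance
    expect_equal(r$extras$or_ci, as.numeric(f$conf.int), tolerance = 1e-2,
                 ignore_attr = TRUE)
  }
})

test_that("Fisher exact handles zero cells and zero margins", {
  r <- fisher_exact(matrix(c(5, 0, 2, 7), 2))
  expect_true(r$extras$zero_cell)
  expect_true(is.infinite(r$extras$or_sample) || is.nan(r$extras$or_sample))
  expect_true(is.finite(r$extras$or_cmle) || r$extras$or_cmle == Inf)
  rz <- fisher_exact(matrix(c(0, 0, 3, 4), 2))
  expect_equal(rz$p_value, 1)
  expect_true(rz$degenerate)
})

test_that("chi-square: hand-computed value, identity, z^2 equivalence", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  r <- suppressWarnings(chi_square(tab))
  expect_equal(r$statistic, 100 / 15)
  # observed equal to expected gives chi-square 0, p 1
  tab0 <- outer(c(10, 20), c(30, 60)) / 30
  r0 <- suppressWarnings(chi_square(tab0))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # agreement with chisq.test (no continuity correction)
  set.seed(20)
  tab <- matrix(rpois(6, 20) + 5, 2, 3)
  r <- chi_square(tab)
  cs <- chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(cs$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, cs$p.value, tolerance = 1e-12)
  # chi-square(1) equals the squared two-proportion z statistic
  t2 <- matrix(c(12, 18, 25, 9), 2)
  p1 <- t2[1, 1] / sum(t2[, 1]); p2 <- t2[1, 2] / sum(t2[, 2])
  pp <- sum(t2[1, ]) / sum(t2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(t2[, 1]) + 1 / sum(t2[, 2])))
  expect_equal(suppressWarnings(chi_square(t2))$statistic, z^2,
               tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(22)
  x <- rexp(15); y <- rexp(18, 0.5)
  f <- function(v) log(v + 1)
  expect_equal(mann_whitney_u(x, y, mode = "asymptotic")$p_value,
               mann_whitney_u(f(x), f(y), mode = "asymptotic")$p_value)
  g <- list(rexp(8), rexp(8), rexp(8, 2))
  expect_equal(kruskal_wallis(g)$p_value,
               kruskal_wallis(lapply(g, f))$p_value)
  expect_equal(spearman_corr(x[1:15], y[1:15])$statistic,
               spearman_corr(f(x[1:15]), f(y[1:15]))$statistic)
})

test_that("test results serialize to JSON with method and options", {
  j <- test_result_json(mann_whitney_u(c(1, 2), c(3, 4)))
  parsed <- jsonlite::fromJSON(j)
  expect_equal(parsed$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(parsed$method, "Mann-Whitney")
})
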