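# Nonparametric test battery against independent oracles.

test_that("normality screen implements the standardized moments", {
  sym <- rep(c(-2, -1, 0, 1, 2), 4)
  ns <- normality_screen(sym)
  expect_equal(ns$z_skew, 0)
  expect_true(ns$normal)

  set.seed(11)
  x <- rexp(26)
  ns2 <- normality_screen(x)
  # independent recomputation of the stated formula
  n <- length(x); m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  expect_equal(ns2$z_skew, G1 / se)
  expect_gt(ns2$z_skew, 1.96)
  expect_false(ns2$normal)

  expect_error(normality_screen(1:5), "n >= 8")
})

test_that("Friedman reproduces the hand-evaluated examples", {
  x <- matrix(rep(c(1, 2, 3), each = 3), nrow = 3)
  tr <- friedman(x, exact = FALSE)
  expect_equal(tr$statistic, 6)
  expect_equal(tr$df, 2)
  expect_equal(tr$p_value, pchisq(6, 2, lower.tail = FALSE))  # ~0.0498
  # exact null: stat = 6 only when all 3 rows order identically, 6/6^3
  expect_equal(friedman(x)$p_value, 1 / 36)

  same <- matrix(5, nrow = 4, ncol = 3)
  tr0 <- friedman(same)
  expect_equal(tr0$statistic, 0)
  expect_equal(tr0$p_value, 1)
  expect_error(friedman(x[1, , drop = FALSE]), "subjects")
})

test_that("Friedman matches stats::friedman.test and a permutation oracle", {
  set.seed(21)
  x <- matrix(rnorm(24), nrow = 8, ncol = 3)      # tie-free
  tr <- friedman(x)
  expect_equal(tr$approx, "exact")
  expect_equal(tr$statistic, unname(stats::friedman.test(x)$statistic))
  p_perm <- oracle_friedman_perm_p(x, B = 20000, seed = 5)
  expect_lt(abs(tr$p_value - p_perm), 0.02)

  # ties: mid-ranks with the tie correction, checked by permutation
  xt <- matrix(sample(1:4, 24, replace = TRUE), nrow = 8)
  p_perm_t <- oracle_friedman_perm_p(xt, B = 20000, seed = 6)
  expect_lt(abs(friedman(xt)$p_value - p_perm_t), 0.02)

  # asymptotic branch beyond n = 8 agrees with stats::friedman.test
  y <- matrix(rnorm(36), nrow = 12, ncol = 3)
  tra <- friedman(y)
  expect_equal(tra$approx, "asymptotic")
  ref <- stats::friedman.test(y)
  expect_equal(tra$statistic, unname(ref$statistic))
  expect_equal(tra$p_value, unname(ref$p.value))
})

test_that("two-group Kruskal-Wallis matches stats::kruskal.test", {
  set.seed(22)
  a <- sample(1:20, 12, replace = TRUE)
  b <- sample(1:20, 9, replace = TRUE)
  tr <- kruskal_wallis(a, b)
  ref <- stats::kruskal.test(list(a, b))
  expect_equal(tr$statistic, unname(ref$statistic))
  expect_equal(tr$p_value, unname(ref$p.value))
  expect_equal(tr$df, 1)
  expect_error(kruskal_wallis(a), "2 groups")
})

test_that("Friedman is invariant under monotone row transforms", {
  set.seed(3)
  x <- matrix(rnorm(30), nrow = 10)
  y <- t(apply(exp(x), 1, function(r) r^3 + 5))
  expect_equal(friedman(x)$statistic, friedman(y)$statistic)
})

test_that("Mann-Whitney handles separation, symmetry and exact nulls", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p_value, 1)

  set.seed(31)
  for (rep in 1:5) {
    a <- sample(1:20, 5, replace = TRUE)
    b <- sample(1:20, 5, replace = TRUE)
    tr <- mann_whitney(a, b)
    expect_equal(tr$approx, "exact")
    expect_equal(tr$statistic, oracle_u(a, b))
    expect_equal(tr$p_value, oracle_mw_exact_p(a, b))
  }
})

test_that("Mann-Whitney asymptotic branch matches wilcox.test", {
  set.seed(41)
  a <- rnorm(16); b <- rnorm(10, 0.8)
  tr <- mann_whitney(a, b)
  expect_equal(tr$approx, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(tr$statistic, unname(ref$statistic))
  expect_equal(tr$p_value, unname(ref$p.value), tolerance = 1e-10)
  # with ties
  a2 <- sample(1:6, 15, replace = TRUE); b2 <- sample(1:6, 12, replace = TRUE)
  tr2 <- mann_whitney(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  expect_equal(tr2$p_value, unname(ref2$p.value), tolerance = 1e-10)
})

test_that("signed-rank test agrees with its sign-flip oracle", {
  set.seed(51)
  a <- sample(1:30, 8); b <- sample(1:30, 8)
  tr <- wilcoxon_signed_rank(a, b)
  expect_equal(tr$approx, "exact")
  expect_equal(tr$p_value, oracle_wsr_exact_p(a, b))
  expect_equal(wilcoxon_signed_rank(a, a)$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "paired")
})

test_that("Spearman correlation, p-value and shared variance", {
  x <- c(1, 3, 9, 12, 20, 21)
  expect_equal(spearman_with_shared_variance(x, x^3)$r_s, 1)
  expect_equal(spearman_with_shared_variance(x, x^3)$shared_pct, 100)

  set.seed(61)
  for (rep in 1:3) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    sp <- spearman_with_shared_variance(x, y)
    expect_equal(sp$r_s, cor(x, y, method = "spearman"))
    expect_equal(sp$shared_pct, round(100 * sp$r_s^2, 1))
    expect_equal(sp$unexplained_pct, round(100 * (1 - sp$r_s^2), 1))
  }
  # exact permutation null at n = 6 equals the independent oracle
  set.seed(62)
  x6 <- rnorm(6); y6 <- rnorm(6)
  sp6 <- spearman_with_shared_variance(x6, y6)
  expect_equal(sp6$p_value, oracle_spearman_exact_p(x6, y6))
  expect_error(spearman_with_shared_variance(1:4, 1:4), ">= 5")
})

test_that("post-hoc family uses the Bonferroni-adjusted alphas", {
  set.seed(71)
  x <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, c("RH", "NR", "UnSc")))
  ph5 <- pairwise_posthoc(x, nominal_alpha = 0.05)
  ph1 <- pairwise_posthoc(x, nominal_alpha = 0.01)
  expect_equal(unique(ph5$alpha_adj), 0.017)
  expect_equal(unique(ph1$alpha_adj), 0.003)
  expect_equal(nrow(ph5), 3)
  same <- matrix(rep(1:10, 3), ncol = 3)
  expect_false(any(pairwise_posthoc(same)$significant))
  # paired alternative runs and reports the same pairs
  phw <- pairwise_posthoc(x, method = "wilcoxon")
  expect_equal(phw$pair, ph5$pair)
})

test_that("tests are invariant to subject ordering", {
  set.seed(81)
  x <- matrix(rpois(30, 20), ncol = 3)
  perm <- x[sample(nrow(x)), ]
  expect_equal(friedman(x)$statistic, friedman(perm)$statistic)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(sample(a), sample(b))$p_value)
})
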