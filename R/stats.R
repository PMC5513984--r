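# Nonparametric test battery. All tests use mid-ranks with the standard
# tie corrections; exact/enumerative null distributions are used at small
# n and asymptotic approximations otherwise, matching common statistical
# software. P-values are two-sided throughout.

test_result <- function(method, statistic, stat_name, p_value, df = NA,
                        alpha = NA, n = NA, approx = NA_character_) {
  structure(list(method = method, statistic = unname(statistic),
                 stat_name = stat_name, df = df,
                 p_value = unname(min(1, max(0, p_value))),
                 alpha = alpha, significant = if (is.na(alpha)) NA
                 else p_value < alpha,
                 n = n, approx = approx),
            class = "wrrc_test_result")
}

#' @export
print.wrrc_test_result <- function(x, ...) {
  dfs <- if (!is.na(x$df)) sprintf("(%g)", x$df) else ""
  sig <- if (isTRUE(x$significant)) " *" else ""
  cat(sprintf("%s: %s%s = %.3f, p = %.3f%s\n", x$method, x$stat_name, dfs,
              x$statistic, x$p_value, sig))
  invisible(x)
}

#' Normality screen by standardized skewness and kurtosis
#'
#' Adjusted Fisher–Pearson skewness (G1) and excess kurtosis (G2) divided
#' by their small-sample standard errors; a sample passes the screen iff
#' both z-values lie within (-1.96, 1.96).
#'
#' @param x numeric sample, n >= 8.
#' @return list with `z_skew`, `z_kurt`, `normal` (flag).
#' @export
normality_screen <- function(x) {
  n <- length(x)
  if (n < 8) stop("normality screen requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)                       # constant sample: symmetric, flat
    return(list(z_skew = 0, z_kurt = 0, normal = TRUE))
  g1 <- mean((x - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  g2 <- mean((x - m)^4) / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  z_s <- G1 / se_skew
  z_k <- G2 / se_kurt
  list(z_skew = z_s, z_kurt = z_k,
       normal = abs(z_s) < 1.96 && abs(z_k) < 1.96)
}

#' Friedman rank test for repeated measures
#'
#' Within-subject mid-ranks with the standard tie correction; chi-squared
#' statistic with k - 1 degrees of freedom. For three conditions with 8 or
#' fewer subjects the p-value comes from the exact permutation null (all
#' within-row orderings, enumerated by dynamic programming over the joint
#' rank-sum distribution); otherwise the asymptotic chi-squared p is used.
#'
#' @param scores n_subjects x k matrix (or data.frame) of scores.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact null
#'   (available for k = 3 only).
#' @return a `wrrc_test_result`.
#' @export
friedman <- function(scores, exact = NULL) {
  x <- as.matrix(scores)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions",
                           call. = FALSE)
  r <- t(apply(x, 1, rank))
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (A == C) 0 else num / (A - C)
  if (is.null(exact)) exact <- n <= 8 && k == 3
  if (exact && k != 3)
    stop("exact Friedman null implemented for 3 conditions only",
         call. = FALSE)
  if (A == C) {
    p <- 1
    meth <- "degenerate"
  } else if (exact) {
    p <- friedman_exact_p(r, stat)
    meth <- "exact"
  } else {
    p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
    meth <- "asymptotic"
  }
  test_result("Friedman", stat, "chi-squared", p,
              df = k - 1, n = n, approx = meth)
}

# Exact permutation p for the tie-corrected Friedman statistic at k = 3:
# the statistic depends on the permuted data only through the column rank
# sums (the per-row squared-rank total is permutation invariant), so the
# joint null distribution of (R1, R2) is built by convolving each row's 6
# equally likely rank assignments. Half-rank units keep everything integer.
friedman_exact_p <- function(r, stat_obs) {
  n <- nrow(r)
  h <- round(2 * r)                     # mid-ranks doubled -> integers
  m <- 6L * n + 1L                      # max doubled rank sum is 6n
  P <- matrix(0, m, m)
  P[1, 1] <- 1
  perm2 <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (i in seq_len(n)) {
    Q <- matrix(0, m, m)
    for (j in 1:6) {
      a <- h[i, perm2[j, 1]]; b <- h[i, perm2[j, 2]]
      Q[(a + 1):m, (b + 1):m] <- Q[(a + 1):m, (b + 1):m] +
        P[1:(m - a), 1:(m - b)] / 6
    }
    P <- Q
  }
  A <- sum(r^2)
  C <- n * 3 * 16 / 4
  tot_h <- sum(h)                       # n * k * (k + 1) in half units
  nz <- which(P > 0, arr.ind = TRUE)
  R1 <- (nz[, 1] - 1) / 2
  R2 <- (nz[, 2] - 1) / 2
  R3 <- tot_h / 2 - R1 - R2
  stats_all <- 2 * ((R1 - n * 2)^2 + (R2 - n * 2)^2 + (R3 - n * 2)^2) /
    (A - C)
  sum(P[nz][stats_all >= stat_obs - 1e-9])
}

#' Kruskal–Wallis rank test
#'
#' Tie-corrected H statistic with k - 1 degrees of freedom and the
#' asymptotic chi-squared p-value. With two groups this is the chi-squared
#' form of the Mann–Whitney comparison (no continuity correction), the
#' variant used for the original pairwise condition post-hocs.
#'
#' @param ... two or more numeric samples.
#' @return a `wrrc_test_result` (statistic is H, reported as chi-squared).
#' @export
kruskal_wallis <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]])) gs <- gs[[1]]
  if (length(gs) < 2) stop("need at least 2 groups", call. = FALSE)
  nj <- lengths(gs)
  if (any(nj < 1)) stop("all groups must be non-empty", call. = FALSE)
  pool <- unlist(gs)
  N <- length(pool)
  rk <- rank(pool)
  Rbar <- tapply(rk, rep(seq_along(gs), nj), mean)
  H <- 12 / (N * (N + 1)) * sum(nj * (Rbar - (N + 1) / 2)^2)
  ties <- table(pool)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  test_result("Kruskal-Wallis", H, "chi-squared",
              stats::pchisq(H, length(gs) - 1, lower.tail = FALSE),
              df = length(gs) - 1, n = nj, approx = "asymptotic")
}

# Mann-Whitney U of sample `a` against `b` from pooled mid-ranks.
mw_u <- function(a, b) {
  n1 <- length(a)
  sum(rank(c(a, b))[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann–Whitney U test
#'
#' Exact permutation null (full enumeration of group assignments) when
#' both groups have 8 or fewer observations, tie-corrected normal
#' approximation with continuity correction otherwise. Two-sided p-values
#' measure deviation of U from its null mean n1*n2/2.
#'
#' @param a,b numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration.
#' @return a `wrrc_test_result` (statistic is U for sample `a`).
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  u <- mw_u(a, b)
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  if (exact) {
    pool <- c(a, b)
    rk <- rank(pool)
    off <- n1 * (n1 + 1) / 2
    us <- utils::combn(n1 + n2, n1, function(ix) sum(rk[ix]) - off)
    p <- mean(abs(us - n1 * n2 / 2) >= abs(u - n1 * n2 / 2) - 1e-9)
    meth <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(c(a, b))
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(test_result("Mann-Whitney", u, "U", 1,
                                      n = c(n1, n2), approx = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "normal"
  }
  test_result("Mann-Whitney", u, "U", p, n = c(n1, n2), approx = meth)
}

#' Wilcoxon signed-rank test (paired)
#'
#' Within-subject alternative to the between-group pairwise test: zeros
#' dropped, mid-ranks of |differences|, exact sign-flip enumeration for
#' 12 or fewer non-zero pairs, tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b paired numeric samples.
#' @return a `wrrc_test_result` (statistic is V, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("samples must be paired", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(test_result("Wilcoxon signed-rank", 0, "V", 1,
                                 n = 0, approx = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  S <- sum(r)
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- mean(abs(vs - S / 2) >= abs(v - S / 2) - 1e-9)
    meth <- "exact"
  } else {
    mu <- S / 2
    sig <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sig
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "normal"
  }
  test_result("Wilcoxon signed-rank", v, "V", p, n = n, approx = meth)
}

#' Spearman correlation with shared variance
#'
#' Mid-rank Spearman correlation; two-sided p-value from the exact
#' permutation null (all n! orderings) for n <= 8 and from the t
#' approximation with n - 2 degrees of freedom otherwise. Shared variance
#' is 100 * r_s^2 reported to one decimal (with its complement, the
#' unexplained percentage).
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration.
#' @return list with `r_s`, `p_value`, `shared_pct`, `unexplained_pct`, `n`.
#' @export
spearman_with_shared_variance <- function(x, y, exact = NULL) {
  n <- length(x)
  if (length(y) != n || n < 5)
    stop("need equal lengths >= 5", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rs <- suppressWarnings(stats::cor(rx, ry))
  if (is.null(exact)) exact <- n <= 8
  if (is.na(rs)) {                            # a constant margin
    rs <- 0
    p <- 1
  } else if (exact) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    den <- sqrt(sum(rxc^2) * sum(ryc^2))
    pm <- permutation_matrix(n)
    rhos <- as.vector(matrix(ryc[pm], nrow(pm)) %*% rxc) / den
    p <- mean(abs(rhos) >= abs(rs) - 1e-9)
  } else if (abs(rs) >= 1) {
    p <- 0
  } else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(r_s = rs, p_value = p,
       shared_pct = round(100 * rs^2, 1),
       unexplained_pct = round(100 * (1 - rs^2), 1), n = n)
}

# All permutations of 1..n as an n! x n matrix (n <= 8).
permutation_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutation_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Pairwise post-hoc tests over three conditions
#'
#' All three condition pairs are compared with the Bonferroni-adjusted
#' alpha `round(nominal_alpha / 3, 3)` (0.05 -> 0.017, 0.01 -> 0.003).
#' The default mirrors the original analysis, which ran two-group
#' Kruskal–Wallis comparisons (reported as chi-squared) on within-subject
#' condition scores; `"mann_whitney"` substitutes the U test and
#' `"wilcoxon"` the methodologically cleaner paired signed-rank
#' alternative.
#'
#' @param scores n x 3 matrix or data.frame (columns = conditions).
#' @param nominal_alpha nominal family alpha.
#' @param method `"kruskal_wallis"` (between-group chi-squared, default),
#'   `"mann_whitney"` or `"wilcoxon"` (paired).
#' @return data.frame: `pair`, `statistic`, `p_value`, `alpha_adj`,
#'   `significant`.
#' @export
pairwise_posthoc <- function(scores, nominal_alpha = 0.05,
                             method = c("kruskal_wallis", "mann_whitney",
                                        "wilcoxon")) {
  method <- match.arg(method)
  x <- as.matrix(scores)
  if (ncol(x) != 3) stop("expected 3 condition columns", call. = FALSE)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("C", 1:3)
  alpha <- round(nominal_alpha / 3, 3)
  pairs <- utils::combn(3, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tr <- switch(method,
                 kruskal_wallis = kruskal_wallis(x[, i1], x[, i2]),
                 mann_whitney = mann_whitney(x[, i1], x[, i2]),
                 wilcoxon = wilcoxon_signed_rank(x[, i1], x[, i2]))
    data.frame(pair = paste(cn[i1], "vs", cn[i2]),
               statistic = tr$statistic, p_value = tr$p_value,
               alpha_adj = alpha, significant = tr$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
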