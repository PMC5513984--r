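# Independent brute-force oracles for the statistical tests, and shared
# fixtures built in code.

# Mann-Whitney U by direct pair counting (no ranks).
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings,
# measuring deviation of U from its null mean.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_obs <- oracle_u(a, b)
  ctr <- n1 * n2 / 2
  us <- utils::combn(n1 + n2, n1, function(ix)
    oracle_u(pool[ix], pool[-ix]))
  mean(abs(us - ctr) >= abs(u_obs - ctr) - 1e-9)
}

# Friedman permutation p by subsampling independent within-row orderings.
oracle_friedman_perm_p <- function(x, B = 20000, seed = 1) {
  stat <- function(m) friedman(m)$statistic
  obs <- stat(x)
  set.seed(seed)
  k <- ncol(x)
  hits <- 0L
  for (b in seq_len(B)) {
    xp <- t(apply(x, 1, sample))
    if (stat(xp) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# Exact Spearman permutation p (all n! orderings of y) for tiny n.
oracle_spearman_exact_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  obs <- abs(stats::cor(rank(x), rank(y)))
  ps <- vapply(perms(seq_along(y)),
               function(ix) abs(stats::cor(rank(x), rank(y[ix]))),
               numeric(1))
  mean(ps >= obs - 1e-9)
}

# Exact sign-flip p for the Wilcoxon signed-rank statistic.
oracle_wsr_exact_p <- function(a, b) {
  d <- (a - b)[a != b]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  S <- sum(r)
  n <- length(d)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(grid %*% r)
  mean(abs(vs - S / 2) >= abs(v_obs - S / 2) - 1e-9)
}

# A small memoized fixture token so synthesis cost is paid once.
fixture_env <- new.env()
fixture_token <- function(ipi = 0.300, stress = 1, seed = 7) {
  key <- sprintf("tok_%g_%d_%d", ipi, stress, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- synth_word_token(ipi, stress, seed = seed)
  fixture_env[[key]]
}

# Random response sheet over the standard design.
random_sheet <- function(seed, p = 0.5) {
  man <- design_manifest(1L)
  set.seed(seed)
  data.frame(listener_id = "LX", sex = "female", trial = man$trial,
             word_id = man$word_id, condition = man$condition,
             syll1_correct = runif(48) < p, syll2_correct = runif(48) < p,
             stringsAsFactors = FALSE)
}

null_effects <- function() {
  eff <- default_effects()
  eff$delta[] <- 0
  eff$sex_rh2_logit <- 0
  eff
}
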