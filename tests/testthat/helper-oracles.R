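# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Bessel functions come from power series, expected
# mutual information from dhyper(), modularity optima from exhaustive
# enumeration, and regression residuals from the normal equations.

# Modified Bessel function of the first kind by power series.
bessel_series <- function(nu, x, terms = 60) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# von Mises log-density at angle e (radians, mean 0) via the series I0.
vm_logdens_oracle <- function(e, kappa) {
  kappa * cos(e) - log(2 * pi * bessel_series(0, kappa))
}

# Circular SD (radians) of a von Mises via the series Bessel ratio.
vm_circ_sd_oracle <- function(kappa) {
  sqrt(-2 * log(bessel_series(1, kappa) / bessel_series(0, kappa)))
}

# All set partitions of n items as label vectors (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  rg <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) {
      out[[length(out) + 1]] <<- rg
      return(invisible())
    }
    for (l in 1:(maxl + 1)) {
      rg[i] <<- l
      rec(i + 1, max(maxl, l))
    }
  }
  rec(1, 0)
  out
}

# Exhaustive modularity optimum over every partition of a small graph.
brute_modularity_optimum <- function(W, gamma = 1) {
  best <- -Inf
  arg <- NULL
  for (p in all_set_partitions(nrow(W))) {
    q <- modularity_q(W, p, gamma)
    if (q > best) {
      best <- q
      arg <- p
    }
  }
  list(q = best, membership = arg)
}

# Expected mutual information under the permutation model, via dhyper().
emi_oracle <- function(l1, l2) {
  n <- length(l1)
  a <- as.vector(table(l1))
  b <- as.vector(table(l2))
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      emi <- emi + (nij / n) * log(n * nij / (a[i] * b[j])) *
        dhyper(nij, a[i], n - a[i], b[j])
    }
  }
  emi
}

ami_oracle <- function(l1, l2) {
  n <- length(l1)
  ct <- table(l1, l2)
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (ct[i, j] > 0) mi <- mi + ct[i, j] / n * log(n * ct[i, j] / (a[i] * b[j]))
  }
  ent <- function(x) { p <- x[x > 0] / n; -sum(p * log(p)) }
  emi <- emi_oracle(l1, l2)
  unname((mi - emi) / ((ent(a) + ent(b)) / 2 - emi))
}

# OLS residuals by explicit normal equations.
ols_residuals_oracle <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  drop(y - X %*% beta)
}

# Welch's heteroscedastic ANOVA by the textbook formula.
welch_anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, var)
  k <- nlevels(groups)
  w <- ns / vs
  W <- sum(w)
  xbar <- sum(w * ms) / W
  S <- sum((1 - w / W)^2 / (ns - 1))
  F <- (sum(w * (ms - xbar)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * S)
  df2 <- (k^2 - 1) / (3 * S)
  list(F = F, df1 = k - 1, df2 = df2,
       p = pf(F, k - 1, df2, lower.tail = FALSE))
}

# Planted small cohort used by several module-detection tests.
small_cohort <- function(seed, n_subjects = 150, module_sizes = c(12, 12),
                         n_subgroups = 2, ...) {
  cfg <- cohort_config(n_subjects = n_subjects,
                       n_rois_active = sum(module_sizes),
                       n_rois_null = 8, module_sizes = module_sizes,
                       n_subgroups = n_subgroups,
                       subgroup_props = rep(1 / n_subgroups, n_subgroups),
                       seed = seed, ...)
  generate_cohort(cfg)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
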