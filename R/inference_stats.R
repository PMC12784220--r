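#' @name inference-stats
#' @title Frequentist and Bayesian statistics for subgroup comparisons
#'
#' @description
#' The subgroup-statistics layer: Welch's heteroscedastic ANOVA and pairwise
#' Welch t-tests (non-pooled variances), chi-squared tests for categorical
#' characteristics, Benjamini-Hochberg FDR adjustment, default-prior Bayes
#' factors (JZS t-test, g-prior one-way ANOVA, stretched-beta correlation),
#' Bayesian R-squared, covariate residualization, a one-pass 3-SD outlier
#' rule, and power analysis for Pearson correlation tests.
NULL

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's (1951) F approximation for unequal group variances and sizes, with
#' Welch-Satterthwaite denominator degrees of freedom. Wraps
#' [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return A list of class `bp_stat`: `statistic` (F), `df1`, `df2`, `p`,
#'   `method`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stopf("each group needs n >= 2")
  vs <- tapply(values, groups, var)
  if (any(vs == 0)) stopf("zero within-group variance in group(s): %s",
                          paste(names(vs)[vs == 0], collapse = ", "))
  res <- oneway.test(values ~ groups, var.equal = FALSE)
  structure(list(statistic = unname(res$statistic),
                 df1 = unname(res$parameter[1]),
                 df2 = unname(res$parameter[2]),
                 p = res$p.value, method = "welch_anova"),
            class = "bp_stat")
}

#' Welch's two-sample t-test (non-pooled variances)
#'
#' @param x,y Numeric samples.
#' @return A `bp_stat` list: `statistic` (t), `df` (Satterthwaite), `p`
#'   (two-sided), `estimate` (mean difference).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                            p = 1, estimate = 0, method = "welch_t"),
                       class = "bp_stat"))
    }
    stopf("both variances are zero")
  }
  res <- t.test(x, y, var.equal = FALSE)
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value,
                 estimate = unname(diff(rev(res$estimate))),
                 method = "welch_t"),
            class = "bp_stat")
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared on a two-way count table; Yates continuity correction
#' is applied to 2x2 tables by default (matching the base-R default the
#' analysis environment uses) and can be disabled.
#'
#' @param table Two-way count matrix/table.
#' @param correct Apply Yates correction for 2x2 tables (default TRUE).
#' @return A `bp_stat` list: `statistic` (X-squared), `df`, `p`.
#' @export
chi_square_independence <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("table has a zero marginal")
  }
  res <- suppressWarnings(chisq.test(table, correct = correct))
  if (any(res$expected <= 0)) stopf("expected counts must be positive")
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value,
                 method = "chi_square"),
            class = "bp_stat")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values aligned to the input order.
#' @export
fdr_bh <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

# Integrate a log-integrand over g in (0, Inf) via the substitution
# g = z / (1 - z), z in (0, 1); normalized by the integrand's maximum.
integrate_g <- function(log_f, rel.tol = 1e-10) {
  zs <- seq(1e-6, 1 - 1e-6, length.out = 200)
  lf <- vapply(zs, function(z) log_f(z / (1 - z)) - 2 * log(1 - z), 0)
  m <- max(lf[is.finite(lf)])
  val <- integrate(function(z) {
    g <- z / (1 - z)
    exp(vapply(g, log_f, 0) - m) / (1 - z)^2
  }, 0, 1, rel.tol = rel.tol, subdivisions = 500L)
  exp(m) * val$value
}

log_invgamma_dens <- function(g, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(g) - scale / g
}

#' JZS Bayes factor for a t-test
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor for a one- or
#' two-sample t-test from the t statistic: Cauchy prior with scale `rscale`
#' on the standardized effect, integrated by adaptive quadrature over the
#' inverse-gamma mixing variable. For two samples the effective sample size
#' is `n1 * n2 / (n1 + n2)`.
#'
#' @param t Observed t statistic.
#' @param n1 First (or only) sample size.
#' @param n2 Optional second sample size.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return BF10 (evidence for the alternative over the null).
#' @export
bf_ttest_jzs <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  if (!is.finite(t)) stopf("t must be finite")
  if (rscale <= 0) stopf("rscale must be positive")
  if (is.null(n2)) {
    nu <- n1 - 1; N <- n1
  } else {
    nu <- n1 + n2 - 2; N <- n1 * n2 / (n1 + n2)
  }
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  log_alt_f <- function(g) {
    -0.5 * log1p(N * g) - (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
      log_invgamma_dens(g, 0.5, rscale^2 / 2)
  }
  integrate_g(log_alt_f) / exp(log_null)
}

# Gauss hypergeometric 2F1(a, b; c; x) by power series (|x| < 1, c > 0).
hyp2f1_series <- function(a, b, cc, x, max_terms = 5000, tol = 1e-15) {
  s <- 1; term <- 1
  for (k in seq_len(max_terms)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((cc + k - 1) * k) * x
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  stopf("hypergeometric series did not converge")
}

# Fisher's exact sampling density of the Pearson correlation r given
# population rho and sample size n (bivariate normal).
dcorr <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r)
  exp(lc) * hyp2f1_series(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Bayes factor for \eqn{\rho \neq 0} with the stretched symmetric beta prior
#' \eqn{p(\rho) \propto (1 - \rho^2)^{1/\mathrm{rscale} - 1}} (the default
#' width 1/3 of the standard default-Bayes-factor implementations). The
#' marginal likelihood integrates the exact sampling density of the sample
#' correlation r (hypergeometric-series evaluation) over the prior by
#' quadrature.
#'
#' @param r Observed Pearson correlation (|r| < 1).
#' @param n Sample size (>= 4).
#' @param rscale Prior width (default 1/3).
#' @return BF10.
#' @export
bf_correlation <- function(r, n, rscale = 1 / 3) {
  if (abs(r) >= 1) stopf("|r| must be < 1")
  if (n < 4) stopf("n must be >= 4")
  if (rscale <= 0) stopf("rscale must be positive")
  a <- 1 / rscale
  Z <- integrate(function(rho) (1 - rho^2)^(a - 1), -1, 1,
                 rel.tol = 1e-12)$value
  num <- integrate(function(rho) {
    vapply(rho, function(p) dcorr(r, p, n), 0) * (1 - rho^2)^(a - 1) / Z
  }, -1, 1, rel.tol = 1e-10, subdivisions = 500L)$value
  num / dcorr(r, 0, n)
}

#' Default g-prior Bayes factor for a one-way ANOVA
#'
#' Bayes factor comparing the one-way fixed-effects model against the
#' grand-mean-only null. Group effects are expressed on an orthonormal
#' sum-to-zero basis with iid `N(0, g sigma^2)` priors and `g` given the
#' default inverse-gamma(1/2, rscale^2/2) mixing distribution (so each
#' standardized effect has a Cauchy(0, rscale) prior); the location and scale
#' are given noninformative priors. Marginalization over `g` is by adaptive
#' quadrature.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param rscale Effect prior scale (default 1/2).
#' @return BF10.
#' @export
bf_oneway_anova <- function(values, groups, rscale = 1 / 2) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stopf("need at least 2 groups")
  n <- length(values)
  Z <- model.matrix(~ groups - 1)
  # orthonormal basis of the sum-to-zero subspace
  Qk <- qr.Q(qr(cbind(1, diag(k))))[, 2:k, drop = FALSE]
  X <- Z %*% Qk
  X <- sweep(X, 2, colMeans(X))                  # remove the grand mean
  y <- values - mean(values)
  S0 <- sum(y^2)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  p <- ncol(X)
  log_bf_g <- function(g) {
    M <- XtX + diag(1 / g, p)
    Sg <- S0 - drop(crossprod(Xty, solve(M, Xty)))
    -0.5 * determinant(diag(p) + g * XtX, logarithm = TRUE)$modulus -
      (n - 1) / 2 * (log(Sg) - log(S0))
  }
  integrate_g(function(g) log_bf_g(g) +
                log_invgamma_dens(g, 0.5, rscale^2 / 2))
}

#' Bayesian R-squared of a linear model
#'
#' Posterior distribution of \eqn{R^2 = \mathrm{Var}(\hat y) /
#' (\mathrm{Var}(\hat y) + \sigma^2)} under the conjugate
#' normal-inverse-gamma linear model with the standard noninformative prior:
#' \eqn{\sigma^2} drawn from its scaled inverse chi-squared posterior and
#' coefficients from their conditional normal posterior. Reports the
#' posterior median.
#'
#' @param y Response vector.
#' @param design Design matrix (an intercept column is added if absent).
#' @param n_draws Posterior draws (default 4000).
#' @param seed Integer seed.
#' @return Posterior median R-squared; the draws are attached as attribute
#'   `"draws"`.
#' @export
bayesian_r2 <- function(y, design, n_draws = 4000, seed = 1L) {
  X <- as.matrix(design)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) X <- cbind(1, X)
  n <- length(y); p <- ncol(X)
  if (n <= p) stopf("need n > p")
  if (qr(X)$rank < p) stopf("rank-deficient design")
  fit <- lm.fit(X, y)
  beta_hat <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - p
  XtXinv <- chol2inv(chol(crossprod(X)))
  R <- chol(XtXinv)
  draws <- with_seed(seed, {
    sig2 <- pmax(rss / stats::rchisq(n_draws, df), 1e-12)
    vapply(seq_len(n_draws), function(i) {
      beta <- beta_hat + sqrt(sig2[i]) * drop(t(R) %*% rnorm(p))
      vfit <- var(drop(X %*% beta))
      vfit / (vfit + sig2[i])
    }, 0)
  })
  out <- median(draws)
  attr(out, "draws") <- draws
  out
}

#' Power of the two-sided Pearson correlation test
#'
#' Bias-corrected Fisher-z approximation: with
#' \eqn{z_\rho = \mathrm{atanh}(\rho) + \rho / (2(n-1))} and critical value
#' \eqn{z_c = \mathrm{atanh}(r_c)}, \eqn{r_c = \sqrt{t_c^2 / (t_c^2 + n -
#' 2)}} from the two-sided alpha critical t at `n - 2` df,
#' \deqn{\mathrm{power} = \Phi((z_\rho - z_c)\sqrt{n-3}) +
#'   \Phi((-z_\rho - z_c)\sqrt{n-3}).}
#'
#' @param rho Population correlation (0 < rho < 1; the test is two-sided
#'   symmetric).
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power (probability).
#' @export
power_correlation <- function(rho, n, alpha = 0.05) {
  if (rho <= 0 || rho >= 1) stopf("rho must lie in (0, 1)")
  if (n < 4) stopf("n must be >= 4")
  tc <- qt(1 - alpha / 2, n - 2)
  rc <- sqrt(tc^2 / (tc^2 + n - 2))
  zc <- atanh(rc)
  zr <- atanh(rho) + rho / (2 * (n - 1))
  pnorm((zr - zc) * sqrt(n - 3)) + pnorm((-zr - zc) * sqrt(n - 3))
}

#' Smallest sample size reaching a target power for a correlation test
#'
#' @inheritParams power_correlation
#' @param power_target Target power (e.g. 0.80).
#' @return Smallest integer n with `power_correlation(rho, n, alpha) >=
#'   power_target`.
#' @export
n_for_power <- function(rho, alpha = 0.05, power_target = 0.80) {
  n <- 4L
  while (power_correlation(rho, n, alpha) < power_target) {
    n <- n + 1L
    if (n > 1e6) stopf("no n below 1e6 reaches the target power")
  }
  n
}

#' Residualize a variable on covariates
#'
#' OLS residuals of `y` on an intercept plus the covariates; the standard
#' preparation for covariate-corrected (e.g. age- or ICV-corrected) group
#' comparisons.
#'
#' @param y Response vector.
#' @param covariates Numeric vector, matrix or data.frame of covariates.
#' @return Residual vector.
#' @export
residualize_covariates <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (length(y) <= ncol(X)) stopf("need n > number of covariates + 1")
  if (qr(X)$rank < ncol(X)) stopf("collinear covariates")
  drop(lm.fit(X, y)$residuals)
}

#' One-pass 3-SD outlier mask
#'
#' Values within `mean +/- 3 * sample SD` are kept; the rule is applied once,
#' without re-iteration. A zero-SD (constant) input keeps everything.
#'
#' @param values Numeric vector (n >= 3).
#' @param n_sd Number of SDs (default 3).
#' @return Logical keep-mask.
#' @export
exclude_outliers_3sd <- function(values, n_sd = 3) {
  if (length(values) < 3) stopf("need n >= 3")
  s <- sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= n_sd * s
}

#' Dichotomize 4-level educational attainment
#'
#' Maps the 4-category education coding to university (level 4) versus all
#' other levels, the split used when some categories are too sparse for
#' chi-squared comparisons.
#'
#' @param levels Integer codes in 1..4 (4 = university or equivalent).
#' @return Integer vector: 1 = university, 0 = other.
#' @export
dichotomize_education <- function(levels) {
  if (any(!levels %in% 1:4)) {
    stopf("unknown education code(s): %s",
          paste(unique(levels[!levels %in% 1:4]), collapse = ", "))
  }
  as.integer(levels == 4)
}

#' Subgroup comparison table
#'
#' For each variable: Welch ANOVA across subgroups, BH-FDR across the
#' variable family, the one-way ANOVA Bayes factor, Bayesian R-squared of the
#' group model, and pairwise Welch t-tests. A `supported` column labels the
#' joint "FDR-adjusted p < 0.05 and BF10 > 3" decision rule; it is a label,
#' not a filter.
#'
#' @param data data.frame of numeric variables (columns) per subject.
#' @param labels Subgroup label per subject.
#' @param covariates Optional covariate matrix; when given, each variable is
#'   residualized on it before testing.
#' @param seed Seed for the Bayesian R-squared draws.
#' @return data.frame with one row per variable.
#' @export
subgroup_statistics <- function(data, labels, covariates = NULL, seed = 1L) {
  labels <- factor(labels)
  rows <- list()
  for (v in names(data)) {
    y <- data[[v]]
    if (!is.null(covariates)) y <- residualize_covariates(y, covariates)
    a <- welch_anova(y, labels)
    bf <- bf_oneway_anova(y, labels)
    br2 <- bayesian_r2(y, model.matrix(~labels)[, -1, drop = FALSE],
                       seed = child_seed(seed, length(rows) + 1))
    prs <- utils::combn(levels(labels), 2)
    tstats <- apply(prs, 2, function(pr) {
      wt <- welch_t(y[labels == pr[1]], y[labels == pr[2]])
      c(t = wt$statistic, p = wt$p)
    })
    rows[[v]] <- data.frame(
      variable = v, F = a$statistic, df1 = a$df1, df2 = a$df2, p = a$p,
      bf10 = bf, bayes_r2 = as.numeric(br2),
      min_pairwise_p = min(tstats["p", ]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out$supported <- out$q < 0.05 & out$bf10 > 3
  rownames(out) <- NULL
  out
}
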