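test_that("Welch ANOVA matches the textbook formula", {
  v <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  g <- rep(1:3, each = 3)
  a <- welch_anova(v, g)
  expect_equal(a$statistic, 62.57143, tolerance = 1e-5)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 4, tolerance = 1e-10)
  o <- welch_anova_oracle(v, g)
  expect_equal(a$statistic, o$F, tolerance = 1e-10)
  expect_equal(a$p, o$p, tolerance = 1e-10)
  set.seed(2)
  for (i in 1:5) {
    vv <- rnorm(30, sd = rep(c(1, 2, 4), each = 10))
    gg <- rep(1:3, each = 10)
    ao <- welch_anova_oracle(vv, gg)
    aa <- welch_anova(vv, gg)
    expect_equal(aa$statistic, ao$F, tolerance = 1e-8)
    expect_equal(aa$df2, ao$df2, tolerance = 1e-8)
  }
})

test_that("Welch ANOVA degenerates correctly", {
  expect_equal(welch_anova(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))$statistic, 0)
  expect_error(welch_anova(c(1, 1, 2, 3), rep(1:2, each = 2)), "zero within-group")
  # k = 2: F equals the square of Welch's t, same denominator df
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15, 1, 2)
  a <- welch_anova(c(x, y), rep(1:2, c(12, 15)))
  t2 <- welch_t(x, y)
  expect_equal(a$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(a$df2, t2$df, tolerance = 1e-10)
})

test_that("Welch ANOVA approaches the classical F on huge balanced equal-variance samples", {
  base <- rnorm(400000)
  v <- c(base, base + 1, base + 2)
  g <- rep(1:3, each = length(base))
  welch <- welch_anova(v, g)$statistic
  classical <- summary(aov(v ~ factor(g)))[[1]]$`F value`[1]
  expect_lt(abs(welch - classical) / classical, 1e-6)
})

test_that("Welch t matches hand formula and is antisymmetric", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  r <- welch_t(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$statistic, -1.549, tolerance = 1e-3)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  expect_equal(r$df, 2.94, tolerance = 1e-2)
  swapped <- welch_t(y, x)
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p, r$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("chi-squared handles Yates correction as the environment default", {
  expect_equal(chi_square_independence(matrix(10, 2, 2))$statistic, 0)
  tab <- matrix(c(20, 10, 10, 20), 2, 2)
  yates <- chi_square_independence(tab)
  expect_equal(yates$statistic, (abs(5) - 0.5)^2 * 4 / 15, tolerance = 1e-10)
  expect_equal(yates$statistic, 5.4, tolerance = 1e-10)
  expect_equal(yates$df, 1)
  expect_equal(chi_square_independence(tab, correct = FALSE)$statistic,
               20 / 3, tolerance = 1e-10)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2)),
               "marginal")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.4, 0.02, 0.9, 0.06)
  ord <- sample(5)
  expect_equal(fdr_bh(p)[ord], fdr_bh(p[ord]))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejection controls the false discovery rate under the null", {
  set.seed(10)
  fdp <- replicate(1000, {
    q <- fdr_bh(runif(20))
    r <- sum(q <= 0.05)
    if (r == 0) 0 else 1          # all discoveries are false under the null
  })
  expect_gt(mean(fdp), 0.02)
  expect_lt(mean(fdp), 0.08)
})

test_that("JZS t-test Bayes factor behaves like the default Cauchy prior", {
  expect_lt(bf_ttest_jzs(0, 50), 1)
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, bf_ttest_jzs, 0, n1 = 25, n2 = 25)
  expect_true(all(diff(bfs) > 0))
  expect_equal(bf_ttest_jzs(-2.2, 30), bf_ttest_jzs(2.2, 30), tolerance = 1e-8)
})

test_that("correlation Bayes factor is symmetric and monotone", {
  expect_equal(bf_correlation(0.4, 60), bf_correlation(-0.4, 60),
               tolerance = 1e-8)
  expect_gt(bf_correlation(0.9, 50), 100)
  rs <- seq(0.1, 0.9, by = 0.2)
  bfs <- vapply(rs, bf_correlation, 0, n = 50)
  expect_true(all(diff(bfs) > 0))
})

test_that("one-way ANOVA Bayes factor matches the JZS t-test at k = 2", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(25, 0.7)
  t_pooled <- t.test(x, y, var.equal = TRUE)$statistic
  bf_t <- bf_ttest_jzs(unname(t_pooled), 20, 25, rscale = sqrt(2) / 2)
  bf_a <- bf_oneway_anova(c(x, y), rep(1:2, c(20, 25)), rscale = 1 / 2)
  expect_lt(abs(bf_t - bf_a) / bf_t, 0.01)
  # location invariance
  bf_shift <- bf_oneway_anova(c(x, y) + 100, rep(1:2, c(20, 25)))
  expect_equal(bf_a, bf_shift, tolerance = 1e-6)
  # near-identical group means at large n favour the null
  set.seed(9)
  z <- rnorm(300)
  expect_lt(bf_oneway_anova(z, rep(1:3, each = 100)), 1 / 3)
  expect_error(bf_oneway_anova(z, rep(1, 300)), "2 groups")
})

test_that("Bayesian R-squared brackets the classical value", {
  set.seed(12)
  y <- rnorm(10)
  expect_equal(as.numeric(bayesian_r2(y, matrix(1, 10, 1))), 0)
  x <- rnorm(500)
  y2 <- 2 * x
  expect_gt(as.numeric(bayesian_r2(y2, cbind(x))), 0.999)
  y3 <- 1 + 0.5 * x + rnorm(500)
  classical <- summary(lm(y3 ~ x))$r.squared
  expect_lt(abs(as.numeric(bayesian_r2(y3, cbind(x), seed = 2)) - classical),
            0.03)
  expect_error(bayesian_r2(y3, cbind(x, x)), "rank-deficient")
})

test_that("correlation power reproduces the published analytic values", {
  expect_equal(round(100 * power_correlation(0.30, 12)), 16)
  expect_equal(round(100 * power_correlation(0.50, 42)), 93)
  expect_equal(round(100 * power_correlation(0.30, 42)), 50)
  expect_identical(n_for_power(0.30, 0.05, 0.80), 85L)
  expect_error(power_correlation(-0.1, 20), "rho")
})

test_that("covariate residualization matches the normal equations", {
  set.seed(13)
  y <- rnorm(5); z <- rnorm(5)
  expect_equal(residualize_covariates(y, z), ols_residuals_oracle(y, cbind(z)),
               tolerance = 1e-10)
  z_orth <- resid(lm(z ~ y))          # orthogonal to y by construction
  expect_equal(residualize_covariates(y, z_orth), y - mean(y),
               tolerance = 1e-10)
  expect_equal(residualize_covariates(y, y), rep(0, 5), tolerance = 1e-10)
  expect_error(residualize_covariates(y, cbind(z, z)), "collinear")
})

test_that("the 3-SD rule is a single pass and affine invariant", {
  expect_true(all(exclude_outliers_3sd(rep(4, 10))))
  set.seed(14)
  v <- c(rnorm(100), 10)
  mask <- exclude_outliers_3sd(v)
  expect_identical(which(!mask), 101L)
  expect_identical(exclude_outliers_3sd(5 * v - 2), mask)
})

test_that("education dichotomization maps university against the rest", {
  expect_identical(dichotomize_education(4L), 1L)
  expect_identical(dichotomize_education(1L), 0L)
  expect_identical(dichotomize_education(c(1, 4, 2, 4, 3)),
                   c(0L, 1L, 0L, 1L, 0L))
  expect_error(dichotomize_education(5), "unknown education")
})

test_that("subgroup statistics label the joint FDR + BF decision rule", {
  set.seed(15)
  g <- rep(1:3, each = 30)
  dat <- data.frame(null_var = rnorm(90), effect_var = rnorm(90) + g)
  out <- subgroup_statistics(dat, g, seed = 3)
  expect_identical(out$variable, c("null_var", "effect_var"))
  expect_true(out$supported[out$variable == "effect_var"])
  expect_false(out$supported[out$variable == "null_var"])
  expect_true(all(out$q >= out$p - 1e-12))
})
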