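vei_truth <- function(d = 8, lam = c(0.5, 0.8, 1.1, 1.4) * 0.05) {
  B <- seq(0.5, 1.5, length.out = d)
  B <- B / exp(mean(log(B)))
  structure(list(G = 4L, d = d, proportions = c(0.31, 0.21, 0.37, 0.11),
                 means = brainprofiles:::default_subgroup_means(4, d),
                 variances = outer(lam, B)),
            class = "bp_profile_model")
}

test_that("parameter counts match enumeration of free parameters", {
  expect_identical(count_params("EII", 1, 1), 2L)
  expect_identical(count_params("VEI", 4, 8), 46L)
  expect_identical(count_params("VVI", 2, 3), 13L)
  expect_identical(count_params("EEI", 3, 5), 2L + 15L + 5L)
  expect_identical(count_params("EVI", 2, 4), 1L + 8L + 1L + 2L * 3L)
  expect_error(count_params("VVV", 2, 3), "unknown family")
})

test_that("G = 1 fits collapse to the constrained single Gaussian", {
  set.seed(7)
  X <- matrix(rnorm(60, sd = rep(c(1, 3), each = 30)), 30, 2)
  for (fam in c("EII", "EEI", "VVI")) {
    f <- fit_profile_model(X, 1, fam, seed = 1)
    expect_equal(unname(f$means[1, ]), colMeans(X), tolerance = 1e-8)
    expect_true(all(f$z == 1))
    v_mle <- colMeans((X - rep(colMeans(X), rep(30, 2)))^2)
    v_fam <- if (fam == "EII") rep(mean(v_mle), 2) else v_mle
    ll <- sum(vapply(1:2, function(j)
      sum(dnorm(X[, j], colMeans(X)[j], sqrt(v_fam[j]), log = TRUE)), 0))
    expect_equal(f$loglik, ll, tolerance = 1e-6)
    expect_equal(f$bic, 2 * f$loglik - f$n_params * log(30), tolerance = 1e-10)
  }
})

test_that("well-separated spherical clusters are classified exactly", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 60
    cl <- rep(1:2, each = n / 2)
    X <- matrix(rnorm(2 * n, sd = 1), n, 2) + 10 * (cl - 1)
    f <- fit_profile_model(X, 2, "EII", seed = s, n_starts = 5)
    expect_equal(adjusted_rand(f$labels, cl), 1)
  }
})

test_that("the EM trace is non-decreasing and score identities hold", {
  sim <- simulate_profile_model(vei_truth(), 150, seed = 3)
  f <- fit_profile_model(sim$X, 3, "VEI", seed = 2, n_starts = 5)
  expect_true(all(diff(f$trace) >= -1e-6))
  expect_equal(f$bic, 2 * f$loglik - f$n_params * log(150), tolerance = 1e-10)
  en <- -sum(f$z[f$z > 0] * log(f$z[f$z > 0]))
  expect_equal(f$icl, f$bic - 2 * en, tolerance = 1e-8)
  expect_lte(f$icl, f$bic + 1e-12)
  expect_true(all(abs(rowSums(f$z) - 1) < 1e-10))
  expect_equal(sum(f$proportions), 1, tolerance = 1e-10)
})

test_that("scores are invariant to permuting component labels", {
  sim <- simulate_profile_model(vei_truth(d = 4), 120, seed = 9)
  f <- fit_profile_model(sim$X, 3, "VVI", seed = 4, n_starts = 5)
  perm <- c(3, 1, 2)
  L <- brainprofiles:::component_logdens(sim$X, f$means[perm, , drop = FALSE],
                                         f$variances[perm, , drop = FALSE])
  L <- sweep(L, 2, log(f$proportions[perm]), "+")
  ll_perm <- sum(brainprofiles:::log_sum_exp_rows(L))
  expect_equal(ll_perm, f$loglik, tolerance = 1e-10)
})

test_that("fitted likelihood matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  sim <- simulate_profile_model(vei_truth(), 300, seed = 21)
  suppressPackageStartupMessages(library(mclust))
  for (fam in c("VEI", "VVI")) {
    ours <- fit_profile_model(sim$X, 4, fam, seed = 3, n_starts = 10)
    theirs <- mclust::Mclust(sim$X, G = 4, modelNames = fam, verbose = FALSE)
    # both are local optimizers; ours should not fall short by more than a hair
    expect_gte(ours$loglik, theirs$loglik - 0.01)
    expect_lt(abs(ours$loglik - theirs$loglik) / abs(theirs$loglik), 0.01)
  }
})

test_that("classification respects the fitted posterior geometry", {
  model <- structure(list(G = 2L, d = 2, proportions = c(0.5, 0.5),
                          means = rbind(c(-5, 0), c(5, 0)),
                          variances = rbind(c(1, 1), c(1, 1))),
                     class = "bp_profile_model")
  at_mean <- classify(model, rbind(c(-5, 0)))
  expect_gt(at_mean$z[1, 1], 0.999)
  midpoint <- classify(model, rbind(c(0, 0)))
  expect_equal(midpoint$z[1, ], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(midpoint$labels, 1L)           # tie broken to lowest index
  set.seed(5)
  r <- classify(model, matrix(rnorm(20), 10, 2))
  expect_equal(rowSums(r$z), rep(1, 10), tolerance = 1e-12)
  expect_error(classify(model, matrix(0, 2, 3)), "expects")
})

test_that("VEI parameters are recovered at n = 400", {
  truth <- vei_truth()
  prop_err <- mean_err <- numeric(6)
  for (s in 1:6) {
    sim <- simulate_profile_model(truth, 400, seed = 700 + s)
    f <- fit_profile_model(sim$X, 4, "VEI", seed = s, n_starts = 8)
    # align components to truth by nearest mean
    ord <- apply(f$means, 1, function(m)
      which.min(colSums((t(truth$means) - m)^2)))
    expect_true(all(sort(ord) == 1:4))
    prop_err[s] <- max(abs(f$proportions - truth$proportions[ord]))
    pooled_sd <- sqrt(mean(truth$variances))
    mean_err[s] <- mean(abs(f$means - truth$means[ord, ])) / pooled_sd
  }
  expect_lt(median(prop_err), 0.05)
  expect_lt(median(mean_err), 0.2)
})

test_that("the bootstrap LRT p-value obeys the add-one rule and has power", {
  set.seed(31)
  X <- matrix(rnorm(50), 50, 1)
  lr <- bootstrap_lrt(X, family = "VVI", G_null = 1, n_boot = 9, seed = 4,
                      n_starts = 2, n_starts_boot = 2, max_iter = 50,
                      tol = 1e-6)
  expect_gte(lr$p_value, 1 / 10)
  expect_gte(lr$lrts, 0)
  # strongly separated two-component data rejects G = 1
  cl <- rep(0:1, each = 30)
  X2 <- matrix(rnorm(60, mean = 8 * cl), 60, 1)
  lr2 <- bootstrap_lrt(X2, family = "VVI", G_null = 1, n_boot = 99, seed = 6,
                       n_starts = 2, n_starts_boot = 2, max_iter = 50,
                       tol = 1e-6)
  expect_lte(lr2$p_value, 0.01)
})
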