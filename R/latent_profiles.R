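#' @name latent-profiles
#' @title Latent profile analysis with diagonal-family Gaussian mixtures
#'
#' @description
#' Latent profile analysis (LPA) models the indicator matrix (here, residual
#' module activity plus overall responsivity) as a finite mixture of
#' multivariate Gaussians with *diagonal* component covariances
#' \eqn{\Sigma_g = \lambda_g B_g} (\eqn{B_g} diagonal, \eqn{\det B_g = 1}),
#' so any between-indicator correlation must be produced by the subgroup
#' structure itself. The six admitted families follow the volume/shape
#' nomenclature: EII and VII (spherical, equal or varying volume), EEI, VEI,
#' EVI and VVI (diagonal, with volume/shape equal or varying across
#' components). Model selection uses BIC and ICL in the "larger is better"
#' convention (`BIC = 2 loglik - n_params log n`), plus a parametric
#' bootstrap likelihood-ratio test for the number of classes.
NULL

profile_families <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI")

#' Free-parameter count of a diagonal-family mixture
#'
#' `(G - 1)` proportions, `G * d` means, plus the family's covariance
#' parameters: EII 1, VII G, EEI d, VEI `G + (d-1)`, EVI `1 + G(d-1)`,
#' VVI `G * d` (shape vectors are constrained to unit determinant).
#'
#' @param family One of `"EII"`, `"VII"`, `"EEI"`, `"VEI"`, `"EVI"`, `"VVI"`.
#' @param G Number of components.
#' @param d Number of indicators.
#' @return Integer parameter count.
#' @export
count_params <- function(family, G, d) {
  covpar <- switch(family,
    EII = 1, VII = G, EEI = d, VEI = G + (d - 1),
    EVI = 1 + G * (d - 1), VVI = G * d,
    stopf("unknown family '%s'", family))
  as.integer((G - 1) + G * d + covpar)
}

# Family-constrained variance M-step. Wg: G x d matrix of responsibility-
# weighted squared deviations per dimension; ng: component weights sums.
mstep_variances <- function(family, Wg, ng, floor_vec) {
  G <- nrow(Wg); d <- ncol(Wg); N <- sum(ng)
  V <- switch(family,
    EII = matrix(sum(Wg) / (N * d), G, d),
    VII = matrix(rowSums(Wg) / (ng * d), G, d),
    EEI = matrix(colSums(Wg) / N, G, d, byrow = TRUE),
    VVI = Wg / ng,
    VEI = {
      lam <- rowSums(Wg) / (ng * d)               # start from VII volumes
      B <- rep(1, d)
      for (it in 1:50) {
        Bnew <- colSums(Wg / lam)
        Bnew <- pmax(Bnew, 1e-300)
        Bnew <- Bnew / exp(mean(log(Bnew)))       # det(B) = 1
        lam_new <- as.vector((Wg %*% (1 / Bnew)) / (ng * d))
        if (max(abs(Bnew - B)) + max(abs(lam_new - lam)) < 1e-10) {
          B <- Bnew; lam <- lam_new; break
        }
        B <- Bnew; lam <- lam_new
      }
      outer(lam, B)
    },
    EVI = {
      Wp <- pmax(Wg, 1e-300)
      geo <- exp(rowMeans(log(Wp)))               # det(Wg)^(1/d)
      Bg <- Wp / geo
      lam <- sum(geo) / N
      lam * Bg
    },
    stopf("unknown family '%s'", family))
  pmax(V, matrix(floor_vec, G, d, byrow = TRUE))
}

# Component log-densities: n x G matrix of log N(x; mu_g, diag(V_g)).
component_logdens <- function(X, means, variances) {
  n <- nrow(X); d <- ncol(X); G <- nrow(means)
  out <- matrix(0, n, G)
  for (g in seq_len(G)) {
    v <- variances[g, ]
    C <- X - rep(means[g, ], rep(n, d))        # column-wise broadcast
    out[, g] <- -0.5 * sum(log(2 * pi * v)) -
      0.5 * drop((C * C) %*% (1 / v))
  }
  out
}

kmeanspp_centers <- function(X, G) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  for (g in seq_len(G - 1)) {
    d2 <- apply(X, 1, function(x) {
      min(colSums((t(X[idx, , drop = FALSE]) - x)^2))
    })
    d2[idx] <- 0
    if (sum(d2) <= 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  X[idx, , drop = FALSE]
}

em_profile <- function(X, G, family, z0, max_iter, tol, floor_vec) {
  n <- nrow(X); d <- ncol(X)
  z <- z0
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ng <- colSums(z)
    if (any(ng < 1e-8)) return(NULL)              # empty component
    props <- ng / n
    means <- crossprod(z, X) / ng
    Wg <- matrix(0, G, d)
    C2 <- vector("list", G)
    for (g in seq_len(G)) {
      C <- X - rep(means[g, ], rep(n, d))
      C2[[g]] <- C * C
      Wg[g, ] <- colSums(z[, g] * C2[[g]])
    }
    variances <- mstep_variances(family, Wg, ng, floor_vec)
    L <- matrix(0, n, G)
    for (g in seq_len(G)) {
      v <- variances[g, ]
      L[, g] <- log(props[g]) - 0.5 * sum(log(2 * pi * v)) -
        0.5 * drop(C2[[g]] %*% (1 / v))
    }
    ll_rows <- log_sum_exp_rows(L)
    ll <- sum(ll_rows)
    if (!is.finite(ll)) return(NULL)
    if (ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      stopf("EM log-likelihood decreased (%.8g -> %.8g)", ll_old, ll)
    }
    trace <- c(trace, ll)
    z <- exp(L - ll_rows)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(proportions = as.vector(props), means = means, variances = variances,
       z = z, loglik = ll, converged = converged, trace = trace)
}

#' Fit a constrained Gaussian mixture (latent profile model)
#'
#' Seeded multi-start EM. Each start draws kmeans++-style centers, runs a
#' short k-means, and uses the hard assignment to initialize EM; the start
#' with the best final log-likelihood wins. Variances are floored at
#' `1e-6` times the pooled per-dimension variance to prevent singularities.
#'
#' @param X Numeric indicator matrix (n x d).
#' @param G Number of latent classes.
#' @param family Covariance family (see [count_params()]).
#' @param seed Integer seed.
#' @param n_starts Number of EM starts (default 20; G = 1 needs one).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A list of class `bp_profile_model`: `family`, `G`, `proportions`,
#'   `means` (G x d), `variances` (G x d diagonals), `z` (responsibilities),
#'   `labels` (MAP), `loglik`, `n_params`, `bic`, `icl`, `converged`,
#'   `trace` (per-iteration log-likelihoods of the winning start).
#' @export
fit_profile_model <- function(X, G, family = "VEI", seed = 1L, n_starts = 20,
                              max_iter = 500, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  family <- match.arg(family, profile_families)
  if (n <= 2 * G) stopf("need n > 2G observations (n = %d, G = %d)", n, G)
  floor_vec <- 1e-6 * apply(X, 2, var)
  floor_vec[floor_vec <= 0] <- 1e-12

  if (G == 1) {
    z0 <- matrix(1, n, 1)
    best <- em_profile(X, 1L, family, z0, max_iter, tol, floor_vec)
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      z0 <- with_seed(child_seed(seed, s), {
        centers <- kmeanspp_centers(X, G)
        km <- tryCatch(suppressWarnings(
          kmeans(X, centers = centers, iter.max = 10)),
          error = function(e) NULL)
        cl <- if (is.null(km)) {
          sample.int(G, n, replace = TRUE)
        } else km$cluster
        z <- matrix(0, n, G)
        z[cbind(seq_len(n), cl)] <- 1
        # soften so no component starts empty
        0.9 * z + 0.1 / G
      })
      fit <- tryCatch(em_profile(X, G, family, z0, max_iter, tol, floor_vec),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) stopf("all EM starts failed (family %s, G = %d)",
                             family, G)
  }
  np <- count_params(family, G, d)
  en <- entropy_of_z(best$z)
  bic <- 2 * best$loglik - np * log(n)
  structure(c(best, list(
    family = family, G = as.integer(G), n = n, d = d, n_params = np,
    bic = bic, icl = bic - 2 * en,
    labels = apply(best$z, 1, which.max)
  )), class = "bp_profile_model")
}

entropy_of_z <- function(z) {
  zz <- z[z > 0]
  -sum(zz * log(zz))
}

#' Classify observations under a fitted profile model
#'
#' Posterior responsibilities and maximum a posteriori labels for new (or the
#' training) data under the fitted mixture; ties go to the lowest class index.
#'
#' @param model A `bp_profile_model`.
#' @param X Indicator matrix with the model's dimensionality.
#' @return List with `z` (n x G responsibilities) and `labels`.
#' @export
classify <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stopf("X has %d columns, model expects %d",
                                ncol(X), model$d)
  L <- component_logdens(X, model$means, model$variances)
  L <- sweep(L, 2, log(model$proportions), "+")
  z <- exp(L - log_sum_exp_rows(L))
  list(z = z, labels = apply(z, 1, which.max))
}

#' Simulate from a fitted profile model
#'
#' @param model A `bp_profile_model`.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return List with `X` (n x d matrix) and `component` labels.
#' @export
simulate_profile_model <- function(model, n, seed = 1L) {
  with_seed(seed, {
    comp <- sample.int(model$G, n, replace = TRUE, prob = model$proportions)
    X <- model$means[comp, , drop = FALSE] +
      matrix(rnorm(n * model$d), n, model$d) *
        sqrt(model$variances[comp, , drop = FALSE])
    list(X = X, component = comp)
  })
}

#' Fit a grid of (G, family) models and select by BIC and ICL
#'
#' @inheritParams fit_profile_model
#' @param G_grid Integer grid of class counts (default 1..9).
#' @param families Families to fit (default all six diagonal/spherical).
#' @param ... Passed to [fit_profile_model()].
#' @return List with `best_bic`, `best_icl` (fitted models), `scores`
#'   (data.frame: family, G, loglik, n_params, bic, icl, converged) and
#'   `fits` (all fitted models, named `family_G`).
#' @export
select_profile_model <- function(X, G_grid = 1:9, families = profile_families,
                                 seed = 1L, ...) {
  if (length(G_grid) == 0 || length(families) == 0) stopf("empty grid")
  fits <- list()
  rows <- list()
  for (fam in families) for (G in G_grid) {
    fit <- tryCatch(
      fit_profile_model(X, G, fam, seed = child_seed(seed, 1000 * G +
                                                       match(fam, profile_families)), ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    key <- paste(fam, G, sep = "_")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(family = fam, G = G, loglik = fit$loglik,
                              n_params = fit$n_params, bic = fit$bic,
                              icl = fit$icl, converged = fit$converged)
  }
  if (length(fits) == 0) stopf("all model fits failed")
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(best_bic = fits[[which.max(scores$bic)]],
       best_icl = fits[[which.max(scores$icl)]],
       scores = scores, fits = fits)
}

#' Parametric bootstrap likelihood-ratio test for the number of classes
#'
#' Tests `G_null` against `G_null + 1` components within one family: the
#' observed statistic is `2 * (loglik_alt - loglik_null)`; its null
#' distribution is estimated by simulating `n_boot` datasets from the fitted
#' null model and refitting both models on each. The p-value uses the add-one
#' rule `p = (1 + #{LRTS* >= LRTS_obs}) / (n_boot + 1)` and so can never be 0.
#'
#' @inheritParams fit_profile_model
#' @param G_null Null number of classes.
#' @param n_boot Number of bootstrap datasets (default 999).
#' @param n_starts_boot EM starts per bootstrap refit (smaller than the
#'   observed-data fit for speed).
#' @param max_fail_rate Error if more than this fraction of bootstrap refits
#'   fail (default 0.2).
#' @return A list of class `bp_lrt`: `G_null`, `G_alt`, `lrts`, `n_boot`,
#'   `p_value`, `lrts_boot`.
#' @export
bootstrap_lrt <- function(X, family = "VEI", G_null = 1, n_boot = 999,
                          seed = 1L, n_starts = 10, n_starts_boot = 4,
                          max_fail_rate = 0.2, ...) {
  X <- as.matrix(X)
  fit0 <- fit_profile_model(X, G_null, family, seed = child_seed(seed, 1),
                            n_starts = n_starts, ...)
  fit1 <- fit_profile_model(X, G_null + 1L, family, seed = child_seed(seed, 2),
                            n_starts = n_starts, ...)
  lrts_obs <- max(0, 2 * (fit1$loglik - fit0$loglik))
  lrts_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- simulate_profile_model(fit0, nrow(X), seed = child_seed(seed, 100 + b))
    b0 <- tryCatch(fit_profile_model(sim$X, G_null, family,
                                     seed = child_seed(seed, 5000 + b),
                                     n_starts = n_starts_boot, ...),
                   error = function(e) NULL)
    b1 <- tryCatch(fit_profile_model(sim$X, G_null + 1L, family,
                                     seed = child_seed(seed, 9000 + b),
                                     n_starts = n_starts_boot, ...),
                   error = function(e) NULL)
    if (!is.null(b0) && !is.null(b1)) {
      lrts_boot[b] <- max(0, 2 * (b1$loglik - b0$loglik))
    }
  }
  fail <- mean(is.na(lrts_boot))
  if (fail > max_fail_rate) {
    stopf("bootstrap refit failure rate %.0f%% exceeds %.0f%%",
          100 * fail, 100 * max_fail_rate)
  }
  ok <- lrts_boot[!is.na(lrts_boot)]
  p <- (1 + sum(ok >= lrts_obs)) / (length(ok) + 1)
  structure(list(G_null = G_null, G_alt = G_null + 1L, lrts = lrts_obs,
                 n_boot = length(ok), p_value = p, lrts_boot = ok),
            class = "bp_lrt")
}
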