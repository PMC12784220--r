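#' @name behavior-mixture
#' @title Three-component mixture model of continuous-report errors
#'
#' @description
#' Continuous-report (delayed estimation) responses are modelled as arising
#' from three sources: a von Mises distribution centred on the probed target
#' (imprecise but correct recall), a von Mises of the same concentration
#' centred on one of the non-probed items (misbinding / swap errors), and a
#' uniform distribution on the circle (guessing). For a trial with response
#' error \eqn{e} (response minus target, wrapped) and non-target errors
#' \eqn{e_i^*}, the density is
#' \deqn{p(e) = p_T \phi_\kappa(e) + \frac{p_{NT}}{m} \sum_{i=1}^{m}
#'   \phi_\kappa(e_i^*) + \frac{p_U}{2\pi},}
#' where \eqn{\phi_\kappa} is the von Mises density with mean 0 and
#' concentration \eqn{\kappa} and \eqn{m} is the number of non-targets.
#' Load-1 trials have no non-targets; their misbinding weight is zero with
#' the remaining weights renormalized.
NULL

vm_logdens <- function(x, kappa) {
  # log von Mises density at angle x (radians, mean 0); exponentially scaled
  # Bessel keeps this finite for large kappa.
  kappa * cos(x) - log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

# A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises.
# Scaled Bessel functions underflow around kappa ~ 1e5; switch to the
# asymptotic expansion well before that.
vm_A <- function(kappa) {
  ifelse(kappa < 1e-12, 0,
         ifelse(kappa > 1e4,
                1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3),
                besselI(pmin(kappa, 1e4), 1, expon.scaled = TRUE) /
                  besselI(pmin(kappa, 1e4), 0, expon.scaled = TRUE)))
}

# Invert A(kappa) = rbar: Best-Fisher starting value + Newton refinement.
vm_kappa_from_rbar <- function(rbar, cap = 500) {
  if (rbar <= 0) return(0)
  if (rbar >= 1) return(cap)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), cap)
  for (i in 1:25) {
    A <- vm_A(k)
    dA <- 1 - A^2 - A / k
    if (!is.finite(dA) || dA <= 0) break
    step <- (A - rbar) / dA
    k <- k - step
    if (!is.finite(k) || k <= 0) { k <- 1e-8; break }
    if (k >= cap) { k <- cap; break }
    if (abs(step) < 1e-12) break
  }
  min(max(k, 0), cap)
}

check_trials <- function(trials) {
  need <- c("load", "target_deg", "resp_deg")
  if (!all(need %in% names(trials))) {
    stopf("trials must have columns %s", paste(need, collapse = ", "))
  }
  ang <- c(trials$target_deg, trials$resp_deg,
           trials$nt1_deg[!is.na(trials$nt1_deg)],
           trials$nt2_deg[!is.na(trials$nt2_deg)])
  if (any(ang < 0 | ang >= 360)) stopf("angles must lie in [0, 360)")
  for (i in seq_len(nrow(trials))) {
    m <- trials$load[i] - 1L
    got <- sum(!is.na(c(trials$nt1_deg[i], trials$nt2_deg[i])))
    if (got < m) stopf("row %d: load %d requires %d non-target angles", i,
                       trials$load[i], m)
  }
  invisible(trials)
}

# Per-trial component log-densities: list(target, nt (matrix), uniform).
trial_component_logdens <- function(trials, kappa) {
  e <- deg2rad(wrap_deg(trials$resp_deg - trials$target_deg))
  lt <- vm_logdens(e, kappa)
  nt <- cbind(trials$nt1_deg, trials$nt2_deg)
  m <- trials$load - 1L
  lnt <- matrix(-Inf, nrow(trials), 2)
  for (j in 1:2) {
    ok <- !is.na(nt[, j]) & m >= j
    if (any(ok)) {
      ej <- deg2rad(wrap_deg(trials$resp_deg[ok] - nt[ok, j]))
      lnt[ok, j] <- vm_logdens(ej, kappa)
    }
  }
  list(target = lt, nt = lnt, unif = rep(-log(2 * pi), nrow(trials)), m = m)
}

#' Log-likelihood of the three-component mixture
#'
#' @param params Named vector or list with `pT`, `pNT`, `pU` (simplex) and
#'   `kappa` (nonnegative shared concentration).
#' @param trials Trial data.frame (`load`, `target_deg`, `resp_deg`,
#'   `nt1_deg`, `nt2_deg`); angles in degrees `[0, 360)`.
#' @return The summed log-likelihood (a scalar).
#' @export
mixture_loglik <- function(params, trials) {
  check_trials(trials)
  if (nrow(trials) == 0) stopf("trials must be nonempty")
  p <- unlist(params)[c("pT", "pNT", "pU", "kappa")]
  if (abs(sum(p[1:3]) - 1) > 1e-6) stopf("pT + pNT + pU must equal 1")
  if (p[["kappa"]] < 0) stopf("kappa must be nonnegative")
  sum(trial_loglik_rows(p, trials))
}

trial_loglik_rows <- function(p, trials) {
  cd <- trial_component_logdens(trials, p[["kappa"]])
  m <- cd$m
  # load-1 rows: pNT forced to 0, weights renormalized
  wT <- ifelse(m == 0, p[["pT"]] / (p[["pT"]] + p[["pU"]]), p[["pT"]])
  wU <- ifelse(m == 0, p[["pU"]] / (p[["pT"]] + p[["pU"]]), p[["pU"]])
  wNT <- ifelse(m == 0, 0, p[["pNT"]])
  L <- cbind(log(wT) + cd$target, log(wU) + cd$unif,
             ifelse(m >= 1, log(wNT / pmax(m, 1)), -Inf) + cd$nt[, 1],
             ifelse(m >= 2, log(wNT / pmax(m, 1)), -Inf) + cd$nt[, 2])
  L[!is.finite(L)] <- -Inf
  log_sum_exp_rows(L)
}

#' Fit the three-component mixture by EM
#'
#' Expectation-maximization over per-trial responsibilities for the target,
#' each non-target, and the uniform component. The M-step updates the weights
#' from mean responsibilities and the shared concentration from the
#' responsibility-weighted mean resultant length by Newton inversion of
#' \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)}. Multiple \eqn{\kappa}
#' initializations are run and the best final log-likelihood returned; the EM
#' log-likelihood trace is checked to be non-decreasing. Because the von
#' Mises components become indistinguishable from the uniform component as
#' kappa approaches 0 (leaving the weights on a flat likelihood ridge), the
#' guessing-only solution (pU = 1, kappa = 0) is reported whenever the full
#' mixture fails to beat it by an AIC margin of one log-likelihood unit per
#' extra free parameter.
#'
#' @param trials Trial data.frame, typically one subject at one load.
#' @param seed Integer seed (initial weight jitter across starts).
#' @param kappa_starts Numeric vector of starting concentrations.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood improves
#'   by less than `tol` or after `max_iter` iterations.
#' @param min_trials Minimum number of trials required.
#' @param kappa_cap Upper bound for the concentration estimate.
#' @return A list of class `bp_mixture_fit`: `pT`, `pNT`, `pU`, `kappa`,
#'   `loglik`, `n_trials`, `converged`, `n_iter`.
#' @export
fit_mixture <- function(trials, seed = 1L, kappa_starts = c(1, 4, 16),
                        max_iter = 500, tol = 1e-6, min_trials = 20,
                        kappa_cap = 500) {
  check_trials(trials)
  n <- nrow(trials)
  if (n < min_trials) stopf("need at least %d trials, got %d", min_trials, n)
  m <- trials$load - 1L
  any_nt <- any(m > 0)

  best <- NULL
  with_seed(seed, {
    for (k0 in kappa_starts) {
      w <- c(pT = 0.6, pNT = if (any_nt) 0.1 else 0, pU = 0.3)
      w <- w + c(runif(1, 0, 0.1), if (any_nt) runif(1, 0, 0.05) else 0,
                 runif(1, 0, 0.1))
      w <- w / sum(w)
      fit <- em_mixture(trials, w, k0, max_iter, tol, kappa_cap, m)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  # identifiability: as kappa -> 0 the von Mises components coincide with the
  # uniform one and the weights sit on a flat ridge where the extra
  # parameters only soak up noise; report the guessing-only solution unless
  # the full mixture beats it by its AIC margin (one unit per extra free
  # parameter: two weights and kappa)
  n_extra <- if (any_nt) 3 else 2
  ll_unif <- -n * log(2 * pi)
  if (best$loglik <= ll_unif + n_extra) {
    best <- list(pT = 0, pNT = 0, pU = 1, kappa = 0, loglik = ll_unif,
                 converged = TRUE, n_iter = best$n_iter)
  }
  best$n_trials <- n
  class(best) <- "bp_mixture_fit"
  best
}

em_mixture <- function(trials, w, kappa, max_iter, tol, kappa_cap, m) {
  n <- nrow(trials)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  any_nt <- any(m > 0)
  repeat {
    iter <- iter + 1L
    cd <- trial_component_logdens(trials, kappa)
    wT <- ifelse(m == 0, w[["pT"]] / (w[["pT"]] + w[["pU"]]), w[["pT"]])
    wU <- ifelse(m == 0, w[["pU"]] / (w[["pT"]] + w[["pU"]]), w[["pU"]])
    wNT <- ifelse(m == 0, 0, w[["pNT"]])
    L <- cbind(log(wT) + cd$target, log(wU) + cd$unif,
               ifelse(m >= 1, log(wNT / pmax(m, 1)), -Inf) + cd$nt[, 1],
               ifelse(m >= 2, log(wNT / pmax(m, 1)), -Inf) + cd$nt[, 2])
    L[!is.finite(L)] <- -Inf
    ll_rows <- log_sum_exp_rows(L)
    ll <- sum(ll_rows)
    if (ll < ll_old - 1e-8) {
      stopf("EM log-likelihood decreased (%.10g -> %.10g)", ll_old, ll)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll

    Z <- exp(L - ll_rows)                     # responsibilities
    zT <- Z[, 1]; zU <- Z[, 2]; zNT <- Z[, 3] + Z[, 4]
    w_new <- c(pT = mean(zT), pNT = if (any_nt) mean(zNT) else 0,
               pU = mean(zU))
    w <- w_new / sum(w_new)
    w <- pmax(w, 1e-10); w <- w / sum(w)

    # weighted mean cosine of errors under the von Mises components
    eT <- deg2rad(wrap_deg(trials$resp_deg - trials$target_deg))
    num <- sum(zT * cos(eT))
    den <- sum(zT)
    nt <- cbind(trials$nt1_deg, trials$nt2_deg)
    for (j in 1:2) {
      ok <- !is.na(nt[, j]) & m >= j
      if (any(ok)) {
        ej <- deg2rad(wrap_deg(trials$resp_deg[ok] - nt[ok, j]))
        num <- num + sum(Z[ok, 2 + j] * cos(ej))
        den <- den + sum(Z[ok, 2 + j])
      }
    }
    rbar <- if (den > 0) max(0, num / den) else 0
    kappa <- vm_kappa_from_rbar(rbar, cap = kappa_cap)
  }
  list(pT = unname(w[["pT"]]), pNT = unname(w[["pNT"]]),
       pU = unname(w[["pU"]]), kappa = kappa, loglik = ll,
       converged = converged, n_iter = iter)
}

#' Precision (inverse circular SD in degrees) from a von Mises concentration
#'
#' Circular SD is \eqn{\sqrt{-2 \ln(I_1(\kappa)/I_0(\kappa))}} radians;
#' precision is the reciprocal of that SD expressed in degrees.
#' `kappa = 0` maps to precision 0 by convention (infinite SD).
#'
#' @param kappa Nonnegative concentration.
#' @return Precision in 1/degrees.
#' @export
precision_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stopf("kappa must be nonnegative")
  sapply(kappa, function(k) {
    if (k < 1e-12) return(0)
    sd_rad <- sqrt(-2 * log(vm_A(k)))
    1 / rad2deg(sd_rad)
  })
}

#' Items in memory implied by a mixture fit
#'
#' The number of stored directions at a given load is taken as
#' `K = load * (1 - pU)`: the uniform (guessing) weight is the probability
#' that the probed item was not in memory, so the complement scaled by load
#' counts the stored items. The model itself does not pin down K; this
#' definition is the package's convention (see the methods vignette).
#'
#' @param fit A `bp_mixture_fit` (or any list with a `pU` field).
#' @param load Memory load (number of presented items).
#' @return Estimated items in memory, in `[0, load]`.
#' @export
items_in_memory <- function(fit, load) {
  load * (1 - fit$pU)
}

#' Fit the mixture per subject and load
#'
#' Convenience driver: splits a trial table by subject and load, fits each
#' cell with [fit_mixture()], and assembles the per-fit summaries. Loads are
#' separate experimental conditions, so each is fitted independently.
#'
#' @param trials Trial data.frame with a `subject_id` column.
#' @param seed Integer seed (fanned out per fit).
#' @param ... Passed to [fit_mixture()].
#' @return data.frame: subject_id, load, pT, pNT, pU, kappa, precision,
#'   k_items, loglik, converged, n_trials.
#' @export
fit_behaviour <- function(trials, seed = 1L, ...) {
  check_trials(trials)
  keys <- unique(trials[, c("subject_id", "load")])
  keys <- keys[order(keys$subject_id, keys$load), , drop = FALSE]
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- trials[trials$subject_id == keys$subject_id[i] &
                    trials$load == keys$load[i], , drop = FALSE]
    f <- fit_mixture(sub, seed = child_seed(seed, i), ...)
    out[[i]] <- data.frame(
      subject_id = keys$subject_id[i], load = keys$load[i],
      pT = f$pT, pNT = f$pNT, pU = f$pU, kappa = f$kappa,
      precision = precision_from_kappa(f$kappa),
      k_items = items_in_memory(f, keys$load[i]),
      loglik = f$loglik, converged = f$converged, n_trials = f$n_trials,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Screen subjects by load-1 performance
#'
#' Flags subjects whose model-implied circular SD at load 1 exceeds a cutoff
#' (default 30 degrees), the usual exclusion for participants who likely did
#' not understand the task. The model-implied SD at the fitted concentration
#' is used rather than the raw mean absolute error.
#'
#' @param fits Output of [fit_behaviour()].
#' @param max_sd_deg Exclusion threshold in degrees.
#' @return Logical vector named by subject: TRUE = keep.
#' @export
screen_load1 <- function(fits, max_sd_deg = 30) {
  f1 <- fits[fits$load == 1, , drop = FALSE]
  if (nrow(f1) == 0) stopf("no load-1 fits to screen")
  sd_deg <- ifelse(f1$precision > 0, 1 / f1$precision, Inf)
  setNames(sd_deg <= max_sd_deg, f1$subject_id)
}
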