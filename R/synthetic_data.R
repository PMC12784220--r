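#' Configuration for a synthetic cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator emulates the structure of a cohort task-fMRI study of visual
#' short-term memory (VSTM): per-subject, per-ROI contrast estimates for a
#' memory-load contrast in which (i) a low-rank global responsivity factor is
#' shared across all task-responsive ROIs, (ii) ROIs fall into planted modules
#' whose activity covaries across subjects, (iii) subjects belong to latent
#' subgroups with distinct module-mean activation profiles, and (iv)
#' continuous-report behavioural errors follow a three-component circular
#' mixture per memory load.
#'
#' The generative model for an active ROI \eqn{r} in module \eqn{m(r)} and
#' subject \eqn{s} of subgroup \eqn{g(s)} is
#' \deqn{\beta_{s,r} = a_s L_r + \mu[g(s), m(r)] + u_{s,m(r)} +
#'   \epsilon_{s,r},}
#' with \eqn{a_s \sim N(1, \sigma_a^2)} the global responsivity,
#' \eqn{L_r \sim U(0.5, 1.5)} positive loadings, \eqn{u_{s,m}} a module-level
#' subject effect with SD `module_factor_sd`, and \eqn{\epsilon} ROI-level
#' noise. Null ROIs are pure noise. Pseudo t-values are a deterministic
#' rescaling `t_scale * beta`; first-level GLM estimation noise is out of
#' scope.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois_active Number of task-responsive ROIs (must equal
#'   `sum(module_sizes)`).
#' @param n_rois_null Number of non-responsive (pure noise) ROIs.
#' @param module_sizes Integer vector of planted module sizes over the active
#'   ROIs.
#' @param n_subgroups Number of planted participant subgroups.
#' @param subgroup_props Subgroup mixing proportions (simplex).
#' @param subgroup_module_means `n_subgroups x n_modules` matrix of module
#'   mean activations (activation units) per subgroup.
#' @param global_factor_sd SD of the per-subject global responsivity factor.
#' @param module_factor_sd SD of the module-level subject effect.
#' @param roi_noise_sd SD of ROI-level noise.
#' @param t_scale Positive scale converting betas to pseudo t-values.
#' @param age_range Two-element numeric, age limits in years (uniform draw,
#'   independent of subgroup by default).
#' @param age_effect_on_subgroup Optional per-subgroup age offsets in years
#'   (off by default: the study found no subgroup age differences).
#' @param covariate_effects Named list describing extra numeric covariates;
#'   each element is a list with fields `offsets` (per-subgroup), `age_slope`
#'   (per year) and `sd` (residual SD).
#' @param behaviour_params Named list with one element per load (`"1"`,
#'   `"2"`, `"3"`), each `c(pT, pNT, pU, kappa)` giving the population
#'   three-component mixture parameters at that load.
#' @param behaviour_jitter_sd SD of per-subject jitter applied to the guessing
#'   probability (clamped to keep the weights on the simplex).
#' @param seed Integer seed; all outputs are reproducible from it.
#'
#' @return A list of class `bp_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 200,
                          n_rois_active = 60,
                          n_rois_null = 20,
                          module_sizes = c(12, 12, 12, 12, 12),
                          n_subgroups = 4,
                          subgroup_props = c(0.31, 0.21, 0.37, 0.11),
                          subgroup_module_means = NULL,
                          global_factor_sd = 0.20,
                          module_factor_sd = 0.20,
                          roi_noise_sd = 0.30,
                          t_scale = 2.0,
                          age_range = c(18, 88),
                          age_effect_on_subgroup = NULL,
                          covariate_effects = default_covariate_effects(n_subgroups),
                          behaviour_params = default_behaviour_params(),
                          behaviour_jitter_sd = 0.04,
                          seed = 1L) {
  n_modules <- length(module_sizes)
  if (is.null(subgroup_module_means)) {
    subgroup_module_means <- default_subgroup_means(n_subgroups, n_modules)
  }
  subgroup_module_means <- as.matrix(subgroup_module_means)
  if (abs(sum(subgroup_props) - 1) > 1e-8) {
    stopf("subgroup_props must sum to 1 (got %.6f)", sum(subgroup_props))
  }
  if (any(subgroup_props < 0)) stopf("subgroup_props must be nonnegative")
  if (length(subgroup_props) != n_subgroups) {
    stopf("subgroup_props must have length n_subgroups")
  }
  if (sum(module_sizes) != n_rois_active) {
    stopf("sum(module_sizes) = %d must equal n_rois_active = %d",
          sum(module_sizes), n_rois_active)
  }
  if (!all(dim(subgroup_module_means) == c(n_subgroups, n_modules))) {
    stopf("subgroup_module_means must be %d x %d", n_subgroups, n_modules)
  }
  for (s in c(global_factor_sd, module_factor_sd, roi_noise_sd,
              behaviour_jitter_sd)) {
    if (s < 0) stopf("all SDs must be nonnegative")
  }
  if (t_scale <= 0) stopf("t_scale must be positive")
  structure(list(
    n_subjects = n_subjects, n_rois_active = n_rois_active,
    n_rois_null = n_rois_null, module_sizes = module_sizes,
    n_subgroups = n_subgroups, subgroup_props = subgroup_props,
    subgroup_module_means = subgroup_module_means,
    global_factor_sd = global_factor_sd, module_factor_sd = module_factor_sd,
    roi_noise_sd = roi_noise_sd, t_scale = t_scale, age_range = age_range,
    age_effect_on_subgroup = age_effect_on_subgroup,
    covariate_effects = covariate_effects,
    behaviour_params = behaviour_params,
    behaviour_jitter_sd = behaviour_jitter_sd,
    seed = as.integer(seed)
  ), class = "bp_cohort_config")
}

#' Default population mixture parameters per memory load
#'
#' Target / non-target / guessing weights and von Mises concentration per
#' load, chosen so the implied items-in-memory means
#' (`K = load * (1 - pU)`) sit at the scale typical of continuous-report VSTM
#' cohorts: K of about 0.95, 1.8, and 2.4 at loads 1-3.
#'
#' @return Named list of `c(pT, pNT, pU, kappa)` per load.
#' @export
default_behaviour_params <- function() {
  list(`1` = c(pT = 0.95, pNT = 0.00, pU = 0.05, kappa = 15),
       `2` = c(pT = 0.85, pNT = 0.05, pU = 0.10, kappa = 12),
       `3` = c(pT = 0.72, pNT = 0.08, pU = 0.20, kappa = 10))
}

#' Default covariate effect structure
#'
#' Two numeric covariates in the spirit of the study's covariate tables:
#' intracranial volume (no subgroup effect, no age trend) and a white-matter
#' mean-kurtosis summary (declining with age, with planted subgroup offsets).
#'
#' @param n_subgroups Number of subgroups.
#' @return Named list usable as `covariate_effects` in [cohort_config()].
#' @export
default_covariate_effects <- function(n_subgroups = 4) {
  offs <- rep(0, n_subgroups)
  mk_offs <- seq(0.04, -0.04, length.out = n_subgroups)
  list(
    icv = list(mean = 1500, offsets = offs, age_slope = 0, sd = 120),
    mean_kurtosis = list(mean = 1.0, offsets = mk_offs,
                         age_slope = -0.003, sd = 0.05)
  )
}

default_subgroup_means <- function(n_subgroups, n_modules) {
  # Sign patterns giving well-separated profiles. Rows are centred so each
  # subgroup has the same mean activity across modules: subgroup membership
  # then shows up only in the *pattern* of module activity, not in overall
  # responsivity, which matches the motivating observation that the global
  # factor carries little subgroup information.
  base <- rbind(c( 1, -1,  1, -1,  0),
                c(-1,  1, -1,  1,  0),
                c( 1,  1, -1, -1,  0),
                c(-1, -1,  1,  1,  0),
                c( 1,  0, -1,  1, -1),
                c(-1,  1,  0, -1,  1))
  if (n_subgroups > nrow(base)) stopf("no default means for >%d subgroups", nrow(base))
  M <- base[seq_len(n_subgroups), , drop = FALSE]
  if (n_modules <= ncol(M)) {
    M <- M[, seq_len(n_modules), drop = FALSE]
  } else {
    M <- cbind(M, matrix(rep_len(t(M), n_subgroups * (n_modules - ncol(M))),
                         nrow = n_subgroups))
  }
  0.5 * (M - rowMeans(M))
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a full cohort from a [cohort_config()]: the subject-by-ROI activation
#' table (betas), the matching pseudo t-value table, a covariate table, and
#' the planted ground truth.
#'
#' @param config A `bp_cohort_config`.
#' @return A list with elements `betas` (subjects x ROIs matrix), `tvalues`
#'   (same shape, `t_scale * betas`), `covariates` (data.frame: subject_id,
#'   age, sex, education, plus configured numeric covariates), and `truth`
#'   (list: `roi_module` with 0 for null ROIs, `subject_subgroup`,
#'   `subject_responsivity`, `loadings`, `behaviour_params` as a subject x
#'   load list matrix of `c(pT, pNT, pU, kappa)`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "bp_cohort_config")) {
    stopf("config must come from cohort_config()")
  }
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_subjects
    n_mod <- length(cf$module_sizes)
    roi_module <- c(rep(seq_len(n_mod), times = cf$module_sizes),
                    rep(0L, cf$n_rois_null))
    n_roi <- length(roi_module)
    roi_ids <- sprintf("roi%03d", seq_len(n_roi))
    subj_ids <- sprintf("s%03d", seq_len(n))

    subgroup <- sample.int(cf$n_subgroups, n, replace = TRUE,
                           prob = cf$subgroup_props)
    a <- rnorm(n, mean = 1, sd = cf$global_factor_sd)
    L <- runif(n_roi, 0.5, 1.5)           # positive loadings, active ROIs only
    u <- matrix(rnorm(n * n_mod, 0, cf$module_factor_sd), n, n_mod)
    eps <- matrix(rnorm(n * n_roi, 0, cf$roi_noise_sd), n, n_roi)

    betas <- eps
    active <- which(roi_module > 0)
    for (r in active) {
      m <- roi_module[r]
      betas[, r] <- a * L[r] + cf$subgroup_module_means[subgroup, m] +
        u[, m] + eps[, r]
    }
    dimnames(betas) <- list(subj_ids, roi_ids)
    tvalues <- betas * cf$t_scale

    age <- runif(n, cf$age_range[1], cf$age_range[2])
    if (!is.null(cf$age_effect_on_subgroup)) {
      age <- age + cf$age_effect_on_subgroup[subgroup]
    }
    sex <- sample(c(0L, 1L), n, replace = TRUE)
    education <- sample.int(4L, n, replace = TRUE)
    covariates <- data.frame(subject_id = subj_ids, age = age, sex = sex,
                             education = education,
                             stringsAsFactors = FALSE)
    for (nm in names(cf$covariate_effects)) {
      ce <- cf$covariate_effects[[nm]]
      covariates[[nm]] <- (ce$mean %||% 0) + ce$offsets[subgroup] +
        ce$age_slope * age + rnorm(n, 0, ce$sd)
    }

    behaviour_params <- vector("list", n)
    for (s in seq_len(n)) {
      pl <- lapply(cf$behaviour_params, function(p) {
        pU <- min(max(p[["pU"]] + rnorm(1, 0, cf$behaviour_jitter_sd), 0.005), 0.9)
        rest <- 1 - pU
        tot <- p[["pT"]] + p[["pNT"]]
        c(pT = rest * p[["pT"]] / tot, pNT = rest * p[["pNT"]] / tot,
          pU = pU, kappa = p[["kappa"]])
      })
      names(pl) <- names(cf$behaviour_params)
      behaviour_params[[s]] <- pl
    }
    names(behaviour_params) <- subj_ids

    truth <- list(
      roi_module = setNames(roi_module, roi_ids),
      subject_subgroup = setNames(subgroup, subj_ids),
      subject_responsivity = setNames(a, subj_ids),
      loadings = setNames(ifelse(roi_module > 0, L, NA_real_), roi_ids),
      behaviour_params = behaviour_params
    )
    list(betas = betas, tvalues = tvalues, covariates = covariates,
         truth = truth)
  })
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution,
# mean direction mu (radians), concentration kappa.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stopf("kappa must be nonnegative")
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  out <- numeric(n)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u3 - 0.5) * acos(f)
    }
  }
  wrap_rad(out + mu)
}

#' Generate continuous-report trials from planted behavioural parameters
#'
#' Samples trials of a continuous-report direction task. On each trial the
#' response is drawn from the three-component mixture: with probability `pT` a
#' von Mises centred on the target, with probability `pNT` a von Mises centred
#' on a uniformly chosen non-target, with probability `pU` uniform on the
#' circle. Load-1 trials have no non-targets, so `pNT` is folded back into the
#' other weights (renormalized).
#'
#' @param truth The `truth` element of [generate_cohort()] output (or any list
#'   with a compatible `behaviour_params` field).
#' @param n_trials_per_load Trials per subject per load.
#' @param seed Integer seed.
#' @param loads Integer loads to simulate (default 1:3).
#' @return A data.frame with columns `subject_id`, `load`, `target_deg`,
#'   `resp_deg`, `nt1_deg`, `nt2_deg` (NA where the load has fewer
#'   non-targets). Angles are degrees in [0, 360).
#' @export
generate_trials <- function(truth, n_trials_per_load, seed, loads = 1:3) {
  bp <- truth$behaviour_params
  if (is.null(bp)) stopf("truth must carry behaviour_params")
  with_seed(seed, {
    rows <- list()
    for (sid in names(bp)) {
      for (ld in loads) {
        p <- bp[[sid]][[as.character(ld)]]
        if (is.null(p)) stopf("no behaviour params for load %s", ld)
        if (p[["kappa"]] < 0) stopf("kappa must be nonnegative")
        if (abs(sum(p[c("pT", "pNT", "pU")]) - 1) > 1e-6) {
          stopf("behaviour weights must lie on the simplex")
        }
        nt_count <- ld - 1L
        w <- p[c("pT", "pNT", "pU")]
        if (nt_count == 0L) {           # no non-targets at load 1
          w["pNT"] <- 0
          w <- w / sum(w)
        }
        nt <- matrix(NA_real_, n_trials_per_load, 2)
        target <- runif(n_trials_per_load, 0, 360)
        if (nt_count > 0) {
          nt[, seq_len(nt_count)] <- runif(n_trials_per_load * nt_count, 0, 360)
        }
        comp <- sample(c("T", "NT", "U"), n_trials_per_load, replace = TRUE,
                       prob = w)
        resp <- numeric(n_trials_per_load)
        for (i in seq_len(n_trials_per_load)) {
          centre <- switch(comp[i],
            T = target[i],
            NT = nt[i, sample.int(nt_count, 1)],
            U = NA_real_)
          resp[i] <- if (is.na(centre)) {
            runif(1, 0, 360)
          } else {
            (rad2deg(rvonmises(1, deg2rad(centre), p[["kappa"]]))) %% 360
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, load = as.integer(ld), target_deg = target,
          resp_deg = resp, nt1_deg = nt[, 1], nt2_deg = nt[, 2],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
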