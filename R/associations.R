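#' Partial correlation with Fisher confidence interval
#'
#' Correlation between the OLS residuals of `x` and `y` on the covariates
#' (plain Pearson correlation when no covariates are given). The p-value uses
#' the t distribution with `n - 2 - k` degrees of freedom and the confidence
#' interval the Fisher z transform with effective df `n - 3 - k`, where `k`
#' is the number of covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate vector/matrix (e.g. age).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `bp_association`: `r`, `ci` (length 2), `p`, `n`,
#'   `k`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  k <- 0L
  scale_x <- sd(x); scale_y <- sd(y)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    k <- ncol(C)
    if (n <= k + 3) stopf("need n > number of covariates + 3")
    x <- residualize_covariates(x, C)
    y <- residualize_covariates(y, C)
  }
  if (scale_x == 0 || scale_y == 0 ||
      sd(x) <= 1e-10 * scale_x || sd(y) <= 1e-10 * scale_y) {
    stopf("degenerate residuals (zero variance)")
  }
  r <- cor(x, y)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(n - 3 - k)
  ci <- tanh(atanh(r) + c(-1, 1) * zcrit * se)
  structure(list(r = r, ci = ci, p = p, n = n, k = k, df = df),
            class = "bp_association")
}

#' Compare two independent correlations (Fisher z-test)
#'
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1 - 3 - k) + 1/(n_2 - 3 - k)}}}
#' with `k` covariates partialled out of each correlation; two-sided p and a
#' 95% CI for the z-scale difference.
#'
#' @param r1,n1,r2,n2 Correlations and sample sizes of the two independent
#'   groups.
#' @param k_covariates Number of covariates (default 0; 1 when age was
#'   partialled out).
#' @param conf_level Confidence level for the z-scale difference CI.
#' @return A list of class `bp_cor_comparison`: `z`, `diff` (z-scale), `ci`,
#'   `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2, k_covariates = 0,
                                        conf_level = 0.95) {
  k <- k_covariates
  if (n1 - 3 - k <= 0 || n2 - 3 - k <= 0) stopf("insufficient n for Fisher test")
  d <- atanh(r1) - atanh(r2)
  se <- sqrt(1 / (n1 - 3 - k) + 1 / (n2 - 3 - k))
  z <- d / se
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(z = z, diff = d, ci = d + c(-1, 1) * zcrit * se,
                 p = 2 * pnorm(-abs(z))),
            class = "bp_cor_comparison")
}

#' Brain-behaviour association suite
#'
#' Age-adjusted partial correlations between each module activity column and
#' each behavioural measure, computed across all participants and separately
#' within each subgroup; subgroups smaller than `min_group_n` are skipped
#' (with the reason logged in the output). BH-FDR is applied within each
#' module-behaviour family across its group-level tests, and retained
#' subgroups are compared pairwise with Fisher z-tests (FDR within each
#' module-behaviour pair).
#'
#' @param activity Module activity table ([module_activity()] output or any
#'   data.frame with `subject_id` and module columns).
#' @param behaviour data.frame with `subject_id` and behavioural measures.
#' @param labels Subgroup label per subject (named by subject id, or aligned
#'   with `activity`).
#' @param covariates data.frame with `subject_id` and the adjustment
#'   covariates (default column `age`).
#' @param modules Module column names to test (default: all `mod*` columns).
#' @param behaviours Behaviour column names (default: all numeric non-id).
#' @param covariate_names Covariates to partial out (default "age").
#' @param min_group_n Minimum subgroup size to analyse (default 13).
#' @return A list: `associations` (data.frame: group, module, behaviour, n,
#'   r, ci_lo, ci_hi, p, q), `comparisons` (pairwise Fisher z rows),
#'   `skipped` (data.frame of skipped groups and reasons).
#' @export
run_association_suite <- function(activity, behaviour, labels, covariates,
                                  modules = NULL, behaviours = NULL,
                                  covariate_names = "age", min_group_n = 13) {
  act <- as.data.frame(activity)
  beh <- as.data.frame(behaviour)
  cov <- as.data.frame(covariates)
  ids <- act$subject_id
  if (is.null(ids)) stopf("activity needs a subject_id column")
  beh <- beh[match(ids, beh$subject_id), , drop = FALSE]
  cov <- cov[match(ids, cov$subject_id), , drop = FALSE]
  lab <- if (!is.null(names(labels))) labels[ids] else labels
  if (length(lab) != length(ids) || any(is.na(lab))) {
    stopf("labels must cover all subjects")
  }
  modules <- modules %||% grep("^mod", names(act), value = TRUE)
  behaviours <- behaviours %||%
    setdiff(names(beh)[vapply(beh, is.numeric, TRUE)], "subject_id")
  C <- as.matrix(cov[, covariate_names, drop = FALSE])

  tab <- table(lab)
  groups <- names(tab)
  retained <- groups[tab >= min_group_n]
  dropped <- setdiff(groups, retained)
  skipped <- data.frame(group = dropped,
                        n = as.integer(tab[dropped]),
                        reason = rep(sprintf("n < %d", min_group_n),
                                     length(dropped)))
  if (length(retained) == 0) stopf("no subgroup meets min_group_n = %d",
                                   min_group_n)
  assoc <- list(); comps <- list()
  for (m in modules) for (b in behaviours) {
    fam <- list()
    for (g in c("all", retained)) {
      sel <- if (g == "all") rep(TRUE, length(ids)) else lab == g
      res <- tryCatch(
        partial_correlation(act[[m]][sel], beh[[b]][sel],
                            C[sel, , drop = FALSE]),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- rbind(skipped, data.frame(
          group = g, n = sum(sel),
          reason = sprintf("%s/%s: %s", m, b, conditionMessage(res))))
        next
      }
      fam[[g]] <- data.frame(group = g, module = m, behaviour = b,
                             n = res$n, r = res$r, ci_lo = res$ci[1],
                             ci_hi = res$ci[2], p = res$p,
                             stringsAsFactors = FALSE)
    }
    if (length(fam)) {
      famdf <- do.call(rbind, fam)
      famdf$q <- fdr_bh(famdf$p)
      assoc[[paste(m, b)]] <- famdf
    }
    # pairwise slope comparisons among retained subgroups
    grs <- intersect(retained, names(fam))
    if (length(grs) >= 2) {
      prs <- utils::combn(grs, 2)
      cmp <- apply(prs, 2, function(pr) {
        a1 <- fam[[pr[1]]]; a2 <- fam[[pr[2]]]
        fz <- compare_correlations_fisher(a1$r, a1$n, a2$r, a2$n,
                                          k_covariates = ncol(C))
        data.frame(module = m, behaviour = b, group1 = pr[1], group2 = pr[2],
                   z = fz$z, ci_lo = fz$ci[1], ci_hi = fz$ci[2], p = fz$p,
                   stringsAsFactors = FALSE)
      })
      cmpdf <- do.call(rbind, cmp)
      cmpdf$q <- fdr_bh(cmpdf$p)
      comps[[paste(m, b)]] <- cmpdf
    }
  }
  out_assoc <- do.call(rbind, assoc)
  rownames(out_assoc) <- NULL
  out_comp <- if (length(comps)) do.call(rbind, comps) else NULL
  if (!is.null(out_comp)) rownames(out_comp) <- NULL
  list(associations = out_assoc, comparisons = out_comp, skipped = skipped)
}
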