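#' Module mean activity and the global responsivity factor
#'
#' For each subject, computes the unweighted mean activation over each
#' retained module's ROIs, together with the overall responsivity: the
#' subject's mean activation across *all* ROIs in the partition's node set
#' (assigned or not), the dominant shared factor in cohort activation tables.
#'
#' @param betas Subjects x ROIs activation matrix (or data.frame with
#'   `subject_id`).
#' @param partition A `bp_partition` (labels 0 = unassigned are excluded from
#'   module means but included in the responsivity average).
#' @return A data.frame of class `bp_module_activity`: `subject_id`, `resp`
#'   (global responsivity), and one `mod<k>` column per retained module
#'   (raw means).
#' @export
module_activity <- function(betas, partition) {
  B <- as_matrix_table(betas, "betas")
  memb <- if (inherits(partition, "bp_partition")) partition$membership else partition
  rois <- names(memb) %||% colnames(B)
  missing_rois <- setdiff(rois, colnames(B))
  if (length(missing_rois)) stopf("betas lack ROIs: %s",
                                  paste(head(missing_rois, 5), collapse = ", "))
  B <- B[, rois, drop = FALSE]
  mods <- sort(unique(memb[memb > 0]))
  if (length(mods) == 0) stopf("partition has no retained modules")
  out <- data.frame(subject_id = rownames(B) %||% as.character(seq_len(nrow(B))),
                    resp = rowMeans(B), stringsAsFactors = FALSE)
  for (m in mods) {
    cols <- rois[memb == m]
    if (length(cols) == 0) stopf("module %s has zero ROIs", m)
    out[[paste0("mod", m)]] <- rowMeans(B[, cols, drop = FALSE])
  }
  class(out) <- c("bp_module_activity", "data.frame")
  out
}

#' Residualize module activity on global responsivity
#'
#' Per module, regresses the module mean on the global responsivity across
#' subjects (ordinary least squares with intercept) and replaces the module
#' column by `residuals + module grand mean`. The add-back restores the
#' interpretability of the values as activity levels (residuals alone are
#' centred at zero) without affecting any subsequent comparisons. The
#' regression R-squared per module is attached as the `"r2"` attribute.
#'
#' @param activity Output of [module_activity()].
#' @return The table with module columns replaced by residualized activity;
#'   attributes `r2` (named per-module R-squared) and `grand_means`.
#' @export
residualize_module_activity <- function(activity) {
  if (!inherits(activity, "bp_module_activity")) {
    stopf("activity must come from module_activity()")
  }
  if (nrow(activity) < 4) stopf("need at least 4 subjects")
  resp <- activity$resp
  if (sd(resp) == 0) stopf("global responsivity has zero variance")
  modcols <- grep("^mod", names(activity), value = TRUE)
  r2 <- setNames(numeric(length(modcols)), modcols)
  gm <- setNames(numeric(length(modcols)), modcols)
  out <- activity
  for (mc in modcols) {
    y <- activity[[mc]]
    fit <- lm(y ~ resp)
    gmean <- mean(y)
    out[[mc]] <- resid(fit) + gmean
    tss <- sum((y - gmean)^2)
    r2[mc] <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 0
    gm[mc] <- gmean
  }
  attr(out, "r2") <- r2
  attr(out, "grand_means") <- gm
  out
}

#' Per-ROI variance explained by global responsivity
#'
#' R-squared of each ROI's activation regressed on the global responsivity,
#' the ROI-level counterpart of the per-module R-squared (useful to judge how
#' dominant the shared factor is before residualization).
#'
#' @inheritParams module_activity
#' @return Named numeric vector of R-squared values, one per ROI.
#' @export
roi_responsivity_r2 <- function(betas, partition) {
  B <- as_matrix_table(betas, "betas")
  memb <- if (inherits(partition, "bp_partition")) partition$membership else partition
  rois <- names(memb) %||% colnames(B)
  B <- B[, rois, drop = FALSE]
  resp <- rowMeans(B)
  apply(B, 2, function(y) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(resid(lm(y ~ resp))^2) / tss
  })
}
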