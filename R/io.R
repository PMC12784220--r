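#' Write a synthetic cohort to disk
#'
#' Writes `activation.csv` and `tvalues.csv` (subject_id + one column per
#' ROI), `covariates.csv`, and `truth.json` into a directory.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- function(M, f) {
    df <- data.frame(subject_id = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  wtab(cohort$betas, "activation.csv")
  wtab(cohort$tvalues, "tvalues.csv")
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(list(
    roi_module = as.list(truth$roi_module),
    subject_subgroup = as.list(truth$subject_subgroup),
    subject_responsivity = as.list(truth$subject_responsivity),
    behaviour_params = truth$behaviour_params
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an activation (or t-value) table
#'
#' @param path CSV with `subject_id` then one column per ROI.
#' @return Numeric matrix with subject row names and ROI column names.
#' @export
read_activation <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_matrix_table(df, path)
}

#' Write / read a trial table
#'
#' @param trials Trial data.frame (see [generate_trials()]).
#' @param path CSV path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_trials(df)
}

#' Write / read a partition table
#'
#' Tab-separated `roi_id`, `module_id` with 0 marking unassigned ROIs.
#'
#' @param partition A `bp_partition` (or named label vector).
#' @param path TSV path.
#' @return `read_partition` returns a named integer label vector.
#' @export
write_partition <- function(partition, path) {
  memb <- if (inherits(partition, "bp_partition")) partition$membership else partition
  df <- data.frame(roi_id = names(memb), module_id = as.integer(memb))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(as.integer(df$module_id), df$roi_id)
}

#' Write behaviour fits
#'
#' @param fits Output of [fit_behaviour()].
#' @param path CSV path.
#' @export
write_behaviour_fits <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
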