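#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one of `simulation` (a
#' [cohort_config()]: the cohort is generated) or `inputs` (a list of file
#' paths: `betas`, `tvalues`, `covariates`, `reference`, optionally `trials`)
#' must be supplied.
#'
#' @param simulation Optional [cohort_config()].
#' @param inputs Optional list of input file paths.
#' @param t_threshold,min_fraction ROI selection settings (see
#'   [select_rois()]).
#' @param gamma_grid Resolution grid for [choose_gamma()].
#' @param min_module_size Minimum ROIs per retained module.
#' @param consensus A [consensus_config()]; the default uses 100 repetitions
#'   and 20 null permutations per gamma, a desk-scale choice that keeps the
#'   full sweep fast while leaving the consensus stable (see the vignette).
#' @param G_grid,families LPA model grid.
#' @param lpa_starts EM starts per LPA fit.
#' @param n_trials_per_load Behavioural trials simulated per subject and load
#'   (simulation mode).
#' @param fit_loads Loads whose mixture fits feed the behaviour table.
#' @param min_group_n Minimum subgroup size for the association suite.
#' @param seed Master seed; every stage derives its own child seed from it.
#' @param out_dir Optional output directory for artefacts.
#' @return A list of class `bp_pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            t_threshold = 1.96, min_fraction = 0.10,
                            gamma_grid = seq(1, 1.5, by = 0.05),
                            min_module_size = 10,
                            consensus = consensus_config(n_repetitions = 100,
                                                         null_permutations = 20),
                            G_grid = 1:6, families = profile_families,
                            lpa_starts = 10,
                            n_trials_per_load = 60, fit_loads = c(1, 3),
                            min_group_n = 13, seed = 1L, out_dir = NULL) {
  if (is.null(simulation) == is.null(inputs)) {
    stopf("supply exactly one of `simulation` or `inputs`")
  }
  structure(list(simulation = simulation, inputs = inputs,
                 t_threshold = t_threshold, min_fraction = min_fraction,
                 gamma_grid = gamma_grid, min_module_size = min_module_size,
                 consensus = consensus, G_grid = G_grid, families = families,
                 lpa_starts = lpa_starts,
                 n_trials_per_load = n_trials_per_load, fit_loads = fit_loads,
                 min_group_n = min_group_n, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "bp_pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Simulate-or-load, ROI selection, inter-subject correlation network,
#' resolution sweep with consensus module detection, module activity and
#' responsivity residualization, latent profile analysis with BIC/ICL
#' selection, subgroup statistics, behavioural mixture fits, and the
#' brain-behaviour association suite. Every stage draws its randomness from
#' a child seed of `config$seed`, so the whole report is reproducible.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `bp_pipeline_report`; see the elements written to
#'   `out_dir` for the table formats.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "bp_pipeline_config")) {
    stopf("config must come from pipeline_config()")
  }
  cf <- config
  simulated <- !is.null(cf$simulation)

  data <- pipeline_stage("load", {
    if (simulated) {
      sim_cfg <- cf$simulation
      sim_cfg$seed <- child_seed(cf$seed, 1)
      cohort <- generate_cohort(sim_cfg)
      trials <- generate_trials(cohort$truth, cf$n_trials_per_load,
                                seed = child_seed(cf$seed, 2),
                                loads = sort(unique(cf$fit_loads)))
      list(betas = cohort$betas, tvalues = cohort$tvalues,
           covariates = cohort$covariates, truth = cohort$truth,
           trials = trials)
    } else {
      list(betas = read_activation(cf$inputs$betas),
           tvalues = read_activation(cf$inputs$tvalues),
           covariates = read.csv(cf$inputs$covariates,
                                 stringsAsFactors = FALSE),
           truth = NULL,
           trials = if (!is.null(cf$inputs$trials))
             read_trials(cf$inputs$trials) else NULL,
           reference = read_partition(cf$inputs$reference))
    }
  })

  selected <- pipeline_stage("select_rois", {
    select_rois(data$tvalues, cf$t_threshold, cf$min_fraction)
  })
  net <- pipeline_stage("intersubject_correlation", {
    intersubject_correlation(data$betas, selected)
  })
  reference <- if (simulated) data$truth$roi_module[selected] else
    data$reference[selected]
  cons_cfg <- cf$consensus
  cons_cfg$seed <- child_seed(cf$seed, 3)
  modsel <- pipeline_stage("choose_gamma", {
    choose_gamma(net, cf$gamma_grid, reference,
                 min_module_size = cf$min_module_size, config = cons_cfg)
  })

  activity <- pipeline_stage("module_activity", {
    module_activity(data$betas, modsel$partition)
  })
  activity_res <- pipeline_stage("residualize", {
    residualize_module_activity(activity)
  })

  indicators <- as.matrix(activity_res[, c("resp",
                                           grep("^mod", names(activity_res),
                                                value = TRUE))])
  lpa <- pipeline_stage("latent_profiles", {
    select_profile_model(indicators, G_grid = cf$G_grid,
                         families = cf$families,
                         seed = child_seed(cf$seed, 4),
                         n_starts = cf$lpa_starts)
  })
  labels <- setNames(lpa$best_bic$labels, activity_res$subject_id)

  behaviour <- NULL
  if (!is.null(data$trials)) {
    behaviour <- pipeline_stage("behaviour_mixture", {
      fits <- fit_behaviour(data$trials, seed = child_seed(cf$seed, 5))
      fits[fits$load %in% cf$fit_loads, , drop = FALSE]
    })
  }

  stats_tab <- pipeline_stage("subgroup_statistics", {
    vars <- data.frame(age = data$covariates$age)
    extra <- setdiff(names(data$covariates),
                     c("subject_id", "age", "sex", "education"))
    for (v in extra) vars[[v]] <- data$covariates[[v]]
    subgroup_statistics(vars, labels, seed = child_seed(cf$seed, 6))
  })

  assoc <- NULL
  if (!is.null(behaviour)) {
    assoc <- pipeline_stage("associations", {
      topload <- max(cf$fit_loads)
      beh <- behaviour[behaviour$load == topload,
                       c("subject_id", "precision", "k_items")]
      run_association_suite(activity_res, beh, labels,
                            covariates = data$covariates,
                            min_group_n = cf$min_group_n)
    })
  }

  report <- structure(list(
    selected_rois = selected,
    selected_gamma = modsel$selected_gamma,
    module_diagnostics = modsel$diagnostics,
    partition = modsel$partition,
    responsivity_r2 = attr(activity_res, "r2"),
    activity = activity_res,
    lpa_scores = lpa$scores,
    chosen_G = lpa$best_bic$G,
    chosen_family = lpa$best_bic$family,
    labels = labels,
    subgroup_stats = stats_tab,
    behaviour = behaviour,
    associations = assoc,
    truth = data$truth,
    provenance = list(seed = cf$seed, simulated = simulated,
                      n_subjects = nrow(data$betas),
                      package_version = as.character(
                        utils::packageVersion("brainprofiles")))
  ), class = "bp_pipeline_report")

  if (!is.null(cf$out_dir)) write_report(report, cf$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_partition(report$partition, file.path(dir, "partition.tsv"))
  write.csv(report$activity, file.path(dir, "module_activity.csv"),
            row.names = FALSE)
  write.csv(report$lpa_scores, file.path(dir, "lpa_scores.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject_id = names(report$labels),
                       label = as.integer(report$labels)),
            file.path(dir, "lpa_labels.csv"), row.names = FALSE)
  write.csv(report$subgroup_stats, file.path(dir, "group_stats.csv"),
            row.names = FALSE)
  if (!is.null(report$behaviour)) {
    write_behaviour_fits(report$behaviour,
                         file.path(dir, "behaviour_fits.csv"))
  }
  if (!is.null(report$associations)) {
    write.csv(report$associations$associations,
              file.path(dir, "associations.csv"), row.names = FALSE)
    if (!is.null(report$associations$comparisons)) {
      write.csv(report$associations$comparisons,
                file.path(dir, "comparisons.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(list(
    selected_gamma = report$selected_gamma,
    chosen_G = report$chosen_G, chosen_family = report$chosen_family,
    responsivity_r2 = as.list(report$responsivity_r2),
    diagnostics = report$module_diagnostics,
    provenance = report$provenance
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
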