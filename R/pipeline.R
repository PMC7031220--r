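#' Contamination filtering in the enforced order
#'
#' Applies the presence-based negative-control removal first and the
#' per-site cross-sample removal second, which is the order the abundance
#' filters must run in, and returns the filtered matrix together with the
#' control-removal report.
#'
#' @param mat an [abundance_matrix()] with a control sample.
#' @param steps subset of `c("control", "cross")` (the order is fixed
#'   regardless of the order given here).
#' @return list `matrix`, `control_report`.
#' @export
filter_study <- function(mat, steps = c("control", "cross")) {
  report <- NULL
  if ("control" %in% steps) {
    res <- remove_control_variants(mat)
    mat <- res$matrix
    report <- res$report
  }
  if ("cross" %in% steps) {
    mat <- remove_cross_sample_variants(mat)
  }
  list(matrix = mat, control_report = report)
}

#' End-to-end demographic breakpoint pipeline
#'
#' Runs the full inference chain on a synthetic multi-site study: simulate
#' the study, reconstruct each site's Ne trajectory from its (true) timed
#' genealogy with the grouped Bayesian skyline, summarise the posterior
#' medians on a calendar grid clipped at 1750 CE, assemble the multi-site
#' Ne table, fit stratified random forests, compute the partial dependence
#' of predictions on the date, and date the demographic change with a
#' single-breakpoint segmented regression started at 1800.
#'
#' @param config a [core_study_config()].
#' @param seed master seed for the study and every downstream stage.
#' @param grid_by calendar grid spacing, years.
#' @param floor_date earliest grid date (default 1750 CE).
#' @param n_groups skyline groups (clamped per site to the number of
#'   coalescent events).
#' @param chain_length,thin,n_chains skyline sampler settings.
#' @param rf_trees,n_splits random-forest settings.
#' @param psi_start,ci_level segmented-regression settings.
#' @return list of class `ne_pipeline`: the study, per-site trajectory
#'   summaries, the Ne table, the `rf_trend` fit, the `pd_curve`, and the
#'   `breakpoint_fit`.
#' @export
run_study_pipeline <- function(config = core_study_config(), seed = 1,
                               grid_by = 2, floor_date = 1750,
                               n_groups = 25, chain_length = 8000,
                               thin = 10, n_chains = 2,
                               rf_trees = 500, n_splits = 10,
                               psi_start = 1800, ci_level = 0.99) {
  study <- generate_core_study(config, seed = seed)
  trajectories <- list()
  fits <- list()
  for (i in seq_along(study$genealogies)) {
    site <- names(study$genealogies)[i]
    tt <- study$genealogies[[site]]
    events <- ape::Ntip(tt$tree) - 1L
    fit <- skyline_fit(tt, n_groups = min(n_groups, events),
                       chain_length = chain_length, thin = thin,
                       n_chains = n_chains,
                       seed = fork_seed(seed, 100L + i))
    root_date <- tt$most_recent_date - max(fit$stats[[1L]]$coal_heights)
    lo <- max(floor_date, ceiling(root_date) + 1)
    grid <- seq(lo, tt$most_recent_date, by = grid_by)
    trajectories[[site]] <- summarize_trajectory(fit, grid)
    fits[[site]] <- fit
  }
  table <- assemble_ne_table(trajectories, floor_date = floor_date)
  rf <- fit_rf(table, n_trees = rf_trees, n_splits = n_splits,
               seed = fork_seed(seed, 200L))
  pd <- partial_dependence(rf, "date_CE")
  fit <- segmented_fit(pd, psi_start = psi_start, ci_level = ci_level)
  structure(list(study = study, skyline_fits = fits,
                 trajectories = trajectories, table = table, rf = rf,
                 pd = pd, breakpoint = fit, seed = seed),
            class = "ne_pipeline")
}

#' @export
print.ne_pipeline <- function(x, ...) {
  cat("Demographic breakpoint pipeline (seed ", x$seed, ")\n", sep = "")
  print(x$study)
  cat(sprintf("  mean RF pseudo-R2: %.3f\n", mean(x$rf$pseudo_r2)))
  cat(sprintf("  estimated breakpoint: %.1f CE [%.1f, %.1f] (true %.0f)\n",
              x$breakpoint$psi, x$breakpoint$ci[1], x$breakpoint$ci[2],
              x$study$truth$breakpoint_date))
  invisible(x)
}
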