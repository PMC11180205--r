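#' Configuration-driven pipeline stages
#'
#' Thin orchestration over the simulator, trace processing and fitting:
#' `run_simulate()` writes a trajectory dataset (trajectory CSV, truth
#' CSV, YAML manifest); `run_analyze()` segments the trajectories and
#' writes per-state dwell tables plus fate and efficiency summaries;
#' `run_fit()` runs the configured dwell-model and secondary fits and
#' writes JSON reports. Configurations are plain lists (or YAML files read
#' with [read_pipeline_config()]); every stochastic stage requires a seed.
#'
#' @param config Pipeline configuration list with elements `out_dir`,
#'   `seed`, `scheme`, `trajectory` and `conditions` (for simulate);
#'   `data_dir` and `thresholds` (for analyze); `fits` (for fit).
#' @return The written file paths, invisibly.
#' @name pipeline
NULL

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

config_scheme <- function(config)
  do.call(kinetic_scheme, config$scheme %||% list())

config_trajconf <- function(config)
  do.call(trajectory_config, config$trajectory %||% list())

config_design <- function(config) {
  stopifnot(length(config$conditions) >= 1)
  lapply(config$conditions, function(cc) do.call(condition, cc))
}

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  if (is.null(config$seed)) stop("config error: seed is required for the ",
                                 "stochastic simulate stage")
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tset <- simulate_dataset(config_design(config), config_scheme(config),
                           config_trajconf(config), seed = config$seed)
  paths <- c(trajectories = file.path(out, "trajectories.csv"),
             truth = file.path(out, "truth.csv"),
             manifest = file.path(out, "manifest.yaml"))
  write_trajectories_csv(tset, paths["trajectories"])
  write_truth_csv(tset, paths["truth"])
  write_manifest(tset, paths["manifest"])
  invisible(list(paths = paths, dataset = tset))
}

#' @rdname pipeline
#' @param tset Optionally, an in-memory `trajectory_set` (skips reading
#'   `data_dir`).
#' @export
run_analyze <- function(config, tset = NULL) {
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tset)) stop("data error: no trajectory set supplied")
  thresholds <- config$thresholds %||% list()
  frame_per_cycle <- tset$config$frame_period *
    length(tset$config$alex_pattern)

  dwell_rows <- list(); fate_rows <- list()
  n_released <- 0L
  for (tr in tset$trajectories) {
    seg <- segment_trace(tr, thresholds)
    n_cyc <- if (nrow(seg)) max(seg$end_frame) else 0L
    for (st in c("elongation", "stall", "intermediate",
                 "post_termination")) {
      ds <- extract_dwells(seg, st, n_cycles = n_cyc)
      if (ds$n)
        dwell_rows[[length(dwell_rows) + 1L]] <- data.frame(
          molecule_id = tr$molecule_id,
          condition = tr$condition$label %||% NA_character_,
          state = st, duration_s = ds$durations, censored = ds$censored)
    }
    if (any(seg$state == "intermediate")) n_released <- n_released + 1L
    tru <- tr$truth
    if (!is.null(tru)) {
      ev <- tru$events
      fate_rows[[length(fate_rows) + 1L]] <- data.frame(
        molecule_id = tr$molecule_id,
        rna_end_frame = round(ev$t_term / frame_per_cycle),
        pol2_end_frame = if (is.finite(ev$pol2_end))
          round(ev$pol2_end / frame_per_cycle) else NA_integer_,
        retained = !is.finite(ev$pol2_end))
    }
  }
  dwells <- do.call(rbind, c(dwell_rows, make.row.names = FALSE))
  utils::write.csv(dwells, file.path(out, "dwells.csv"),
                   row.names = FALSE)
  fates <- classify_pol2_fate(
    do.call(rbind, c(fate_rows, make.row.names = FALSE)),
    frame_period = frame_per_cycle)
  eff <- termination_efficiency(n_released, length(tset$trajectories))
  summary_tab <- data.frame(category = names(fates$counts),
                            count = as.integer(fates$counts))
  utils::write.table(summary_tab, file.path(out, "fates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fate_counts = as.list(fates$counts),
         after_mean_s = fates$after_mean, after_se_s = fates$after_se,
         termination_efficiency = eff$fraction,
         termination_efficiency_se = eff$se),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dwells = dwells, fates = fates, efficiency = eff))
}

#' @rdname pipeline
#' @param dwells Long dwell table from [run_analyze()] (columns
#'   `condition`, `state`, `duration_s`, `censored`).
#' @export
run_fit <- function(config, dwells) {
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  for (spec in config$fits) {
    st <- spec$state %||% "stall"
    d <- dwells[dwells$state == st & !dwells$censored, , drop = FALSE]
    conds <- split(d$duration_s, d$condition)
    conds <- conds[lengths(conds) >= 10]
    hists <- lapply(conds, build_histogram)
    S <- spec$S %||% rep(NA_real_, length(hists))
    fit <- fit_global_ls(hists, spec$model_id, S = S,
                         hold = spec$hold %||% list(),
                         share = spec$share %||% "k2")
    reports[[spec$name %||% spec$model_id]] <- list(
      model_id = spec$model_id, state = st,
      estimates = as.list(fit$estimates), ses = as.list(fit$ses),
      reduced_chisq = fit$reduced_chisq,
      n = vapply(hists, `[[`, numeric(1), "n"))
  }
  path <- file.path(out, "fits.json")
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA)
  invisible(reports)
}
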