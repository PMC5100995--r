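## End-to-end pipeline: synthesize -> fit -> error analysis -> functional
## experiments, driven by a single (YAML or list) configuration.

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list. Recognised top-level
#'   fields: `seed`, `out_dir`, `synth` (arguments of [synthetic_spec()]),
#'   `fit` (arguments of [fit_config()]), `errors`
#'   (`stat_replicates`, `sys_samples`; 0 disables a stage), `experiments`
#'   (`epsp`, `spikes`, `velocity` logicals plus protocol arguments such
#'   as `n_trials`, `N_grid`), `sweeps_dir` (use recorded sweeps from
#'   [write_sweeps()] instead of synthesizing), `swc` (use a morphology
#'   file instead of generating one).
#' @return validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1, out_dir = NULL, synth = list(), fit = list(),
                   errors = list(stat_replicates = 0, sys_samples = 0),
                   experiments = list(epsp = FALSE, spikes = FALSE,
                                      velocity = FALSE),
                   sweeps_dir = NULL, swc = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("sweeps_dir", "swc"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configured path does not exist: ", config[[f]])
  config
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: synthetic-data generation (or loading of
#' morphology/sweeps), passive-parameter fitting, statistical and
#' systematic error estimation, and the functional protocols. Every stage
#' records the seed it ran under; reruns with the same config and seed are
#' byte-identical apart from the timestamp.
#'
#' @param config a config list or YAML path (see [read_run_config()]).
#' @return the report list (also written as JSON to `out_dir` when set).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  report <- list(seed = config$seed, timestamp = format(Sys.time()))

  synth_args <- utils::modifyList(list(seed = config$seed), config$synth)
  spec <- do.call(synthetic_spec, synth_args)
  morph <- if (!is.null(config$swc)) load_swc(config$swc)
           else gen_morphology(spec)
  report$morphology <- morph_summary(morph, spec$F, spec$spine_start_um)
  report$morphology$sections_by_kind <-
    as.list(report$morphology$sections_by_kind)

  sweeps <- if (!is.null(config$sweeps_dir)) read_sweeps(config$sweeps_dir)
            else gen_transients(morph, spec)
  truth <- attr(sweeps, "truth")
  if (!is.null(truth)) report$truth <- truth

  fit_args <- utils::modifyList(list(seed = config$seed), config$fit)
  fcfg <- do.call(fit_config, fit_args)
  fit <- fit_passive(morph, sweeps, fcfg)
  report$fit <- list(cm_uF_cm2 = fit$params$cm, rm_Ohm_cm2 = fit$params$rm,
                     ra_Ohm_cm = fit$params$ra, rmsd_mV = fit$rmsd_mV,
                     validation = fit$validation)

  amps <- vapply(sweeps, function(s) s$amp_pA, numeric(1))
  fit_ss <- sweeps[[if (any(amps > 0)) which.max(amps) else which.min(amps)]]
  if (config$errors$stat_replicates > 0) {
    se <- statistical_errors(morph, fit_ss,
                             bootstrap_plan(ncol(fit_ss$v_mV),
                                            config$errors$stat_replicates,
                                            seed = config$seed),
                             fcfg, fit = fit)
    report$statistical_errors <- list(sd = as.list(se$sd),
                                      sd_rel_pct = as.list(se$sd_rel_pct),
                                      n_failed = length(se$failed))
  }
  if (config$errors$sys_samples > 0) {
    sy <- systematic_errors(morph, fit_ss,
                            systematic_error_spec(
                              n_samples = config$errors$sys_samples,
                              seed = config$seed),
                            fcfg, fit = fit)
    report$systematic_errors <- list(sd = as.list(sy$sd),
                                     sd_rel_pct = as.list(sy$sd_rel_pct))
  }

  ex <- config$experiments
  if (isTRUE(ex$epsp)) {
    report$epsp <- epsp_transfer(morph, rm = fit$params$rm,
                                 ra = fit$params$ra,
                                 F = spec$F,
                                 spine_start_um = spec$spine_start_um)
  }
  if (isTRUE(ex$spikes)) {
    args <- list(morph = morph, rm = fit$params$rm, ra = fit$params$ra,
                 F = spec$F, spine_start_um = spec$spine_start_um,
                 seed = config$seed)
    if (!is.null(ex$n_trials)) args$n_trials <- ex$n_trials
    if (!is.null(ex$N_grid)) args$N_grid <- ex$N_grid
    s_lo <- do.call(synapses_to_spike, c(args, list(cm = 0.45)))
    s_hi <- do.call(synapses_to_spike, c(args, list(cm = 0.9)))
    report$synapses_to_spike <- list(
      n50_cm_low = s_lo$n50, n50_cm_high = s_hi$n50,
      curve_cm_low = s_lo$curve, curve_cm_high = s_hi$curve)
  }
  if (isTRUE(ex$velocity)) {
    av <- axon_velocity(morph, rm = fit$params$rm, ra = fit$params$ra,
                        F = spec$F, spine_start_um = spec$spine_start_um)
    report$axon_velocity <- list(table = av,
                                 pct_increase = attr(av, "pct_increase"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
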