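## Uncertainty of fitted parameters: balanced-bootstrap statistical errors
## and morphology-perturbation systematic errors.

#' Balanced bootstrap plan
#'
#' @param n_sweeps number of recorded sweeps per stimulus (50 in the
#'   standard protocol).
#' @param n_replicates number of resampled averages (default 100).
#' @param seed RNG seed.
#' @export
bootstrap_plan <- function(n_sweeps = 50, n_replicates = 100, seed = 1) {
  stopifnot(n_sweeps >= 1, n_replicates >= 1)
  structure(list(n_sweeps = n_sweeps, n_replicates = n_replicates,
                 seed = seed), class = "bootstrap_plan")
}

#' Balanced resampling of a sweep set
#'
#' Builds the balanced index matrix: the indices `1..n_sweeps` are
#' repeated `n_replicates` times, randomly permuted as one pool, and
#' partitioned into `n_replicates` rows of `n_sweeps` indices. Every sweep
#' therefore appears exactly `n_replicates` times overall, which makes the
#' grand mean of the replicate averages equal the overall sweep mean
#' exactly.
#'
#' @param ss a [sweep_set()].
#' @param plan a [bootstrap_plan()] with `n_sweeps` matching the set.
#' @return list of `n_replicates` resampled averaged transients (each as
#'   returned by [average_transient()]); the index matrix is attached as
#'   attribute `"index_matrix"`.
#' @export
balanced_resample <- function(ss, plan) {
  stopifnot(inherits(ss, "sweep_set"), inherits(plan, "bootstrap_plan"))
  if (ncol(ss$v_mV) != plan$n_sweeps)
    stop("plan$n_sweeps must equal the sweep count")
  with_seed(plan$seed, {
    pool <- sample(rep(seq_len(plan$n_sweeps), plan$n_replicates))
  })
  idx <- matrix(pool, nrow = plan$n_replicates, ncol = plan$n_sweeps,
                byrow = TRUE)
  reps <- lapply(seq_len(plan$n_replicates), function(r) {
    sub <- sweep_set(ss$time_ms, ss$v_mV[, idx[r, ], drop = FALSE],
                     ss$amp_pA, ss$delay_ms, ss$dur_ms, ss$junction_mV)
    average_transient(sub)
  })
  attr(reps, "index_matrix") <- idx
  reps
}

## refit a single averaged transient, warm-started at the full-data best
refit_average <- function(avg, comps_template, morph, config, start) {
  ss1 <- sweep_set(avg$time_ms, matrix(avg$v_mV, ncol = 1), avg$amp_pA,
                   avg$delay_ms, avg$dur_ms)
  fit_passive(morph, ss1, config, start = start)
}

#' Statistical errors of the fitted parameters (balanced bootstrap)
#'
#' Refits every balanced-bootstrap replicate average (warm-started at the
#' full-data best fit) and reports the standard deviation of each fitted
#' parameter across replicates, absolute and relative.
#'
#' @param morph,sweeps,config as [fit_passive()]; `sweeps` is the single
#'   [sweep_set()] used for fitting.
#' @param plan a [bootstrap_plan()].
#' @param fit optional precomputed full-data `fit_result` (computed if
#'   missing).
#' @return list: `fit` (full-data result), `sd` and `sd_rel_pct` named
#'   vectors over `c(cm, rm, ra)`, `replicates` (per-replicate fitted
#'   values), `failed` (indices of non-converged replicates, if any).
#' @export
statistical_errors <- function(morph, sweeps, plan = bootstrap_plan(),
                               config = fit_config(), fit = NULL) {
  if (inherits(sweeps, "list")) sweeps <- sweeps[[1]]
  if (is.null(fit)) fit <- fit_passive(morph, sweeps, config)
  start <- c(cm = fit$params$cm, rm = fit$params$rm, ra = fit$params$ra)
  reps <- balanced_resample(sweeps, plan)
  vals <- matrix(NA_real_, length(reps), 3,
                 dimnames = list(NULL, c("cm", "rm", "ra")))
  failed <- integer(0)
  for (r in seq_along(reps)) {
    fr <- tryCatch(refit_average(reps[[r]], NULL, morph, config, start),
                   error = function(e) NULL)
    if (is.null(fr) || !fr$converged) failed <- c(failed, r)
    if (!is.null(fr))
      vals[r, ] <- c(fr$params$cm, fr$params$rm, fr$params$ra)
  }
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  means <- colMeans(vals, na.rm = TRUE)
  list(fit = fit, sd = sds, sd_rel_pct = 100 * sds / means,
       replicates = as.data.frame(vals), failed = failed)
}

#' Systematic-error specification
#'
#' The five independent morphological error sources, each sampled once per
#' synthetic morphology from a normal distribution centred on the original
#' reconstruction: a multiplicative length scale (SD 0.05), an additive
#' diameter error (SD 0.3 um), a multiplicative diameter error (SD 0.1),
#' the spine factor F (SD 0.4) and the spine-territory start distance
#' (SD 30 um, truncated at 0).
#'
#' @param sd_length_scale,sd_diam_add_um,sd_diam_scale,sd_F,sd_start_um
#'   standard deviations of the five error variables.
#' @param n_samples number of perturbed morphologies to refit.
#' @param min_diam_um floor applied to perturbed diameters.
#' @param seed RNG seed.
#' @export
systematic_error_spec <- function(sd_length_scale = 0.05, sd_diam_add_um = 0.3,
                                  sd_diam_scale = 0.1, sd_F = 0.4,
                                  sd_start_um = 30, n_samples = 100,
                                  min_diam_um = 0.1, seed = 1) {
  stopifnot(sd_length_scale >= 0, sd_diam_add_um >= 0, sd_diam_scale >= 0,
            sd_F >= 0, sd_start_um >= 0, n_samples >= 1)
  structure(list(sd_length_scale = sd_length_scale,
                 sd_diam_add_um = sd_diam_add_um,
                 sd_diam_scale = sd_diam_scale, sd_F = sd_F,
                 sd_start_um = sd_start_um, n_samples = n_samples,
                 min_diam_um = min_diam_um, seed = seed),
            class = "systematic_error_spec")
}

#' Apply one draw of systematic morphological errors
#'
#' Scales all section lengths by `length_scale` (coordinates scaled about
#' the soma), then perturbs diameters additively and multiplicatively
#' (in that order), clipping at `min_diam_um`.
#'
#' @param morph a [morphology()] object.
#' @param length_scale multiplicative factor on all coordinates.
#' @param diam_add_um additive diameter perturbation, um.
#' @param diam_scale multiplicative diameter perturbation.
#' @param min_diam_um diameter floor, um.
#' @return perturbed morphology; attribute `"n_clipped"` counts diameters
#'   that hit the floor.
#' @export
perturb_morphology <- function(morph, length_scale = 1, diam_add_um = 0,
                               diam_scale = 1, min_diam_um = 0.1) {
  soma <- morph$sections[[as.character(morph$soma_id)]]
  origin <- soma$points[1, 1:3]
  n_clipped <- 0L
  secs <- lapply(morph$sections, function(s) {
    pts <- s$points
    pts[, 1:3] <- sweep(sweep(pts[, 1:3, drop = FALSE], 2, origin),
                        1, rep(length_scale, nrow(pts)), "*")
    pts[, 1:3] <- sweep(pts[, 1:3, drop = FALSE], 2, origin, "+")
    d <- (pts[, "diam"] + diam_add_um) * diam_scale
    n_clipped <<- n_clipped + sum(d < min_diam_um)
    pts[, "diam"] <- pmax(d, min_diam_um)
    section(s$id, s$kind, pts, s$parent, s$parent_pos)
  })
  out <- morphology(unname(secs), metadata = morph$metadata)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Systematic errors of the fitted parameters
#'
#' For each sample, draws the five error variables, perturbs the
#' morphology (and the spine correction's F and start distance), refits
#' the original averaged transient on the perturbed model (warm-started at
#' the full-data best fit), and reports the SD of each parameter across
#' samples.
#'
#' @param morph,sweeps,config as [fit_passive()].
#' @param spec a [systematic_error_spec()].
#' @param fit optional precomputed full-data `fit_result`.
#' @return list: `fit`, `sd`, `sd_rel_pct`, `samples` (per-sample fitted
#'   values and the drawn error variables), `n_clipped` total.
#' @export
systematic_errors <- function(morph, sweeps, spec = systematic_error_spec(),
                              config = fit_config(), fit = NULL) {
  if (inherits(sweeps, "list")) sweeps <- sweeps[[1]]
  if (is.null(fit)) fit <- fit_passive(morph, sweeps, config)
  start <- c(cm = fit$params$cm, rm = fit$params$rm, ra = fit$params$ra)
  avg <- average_transient(sweeps)
  draws <- with_seed(spec$seed, data.frame(
    length_scale = stats::rnorm(spec$n_samples, 1, spec$sd_length_scale),
    diam_add = stats::rnorm(spec$n_samples, 0, spec$sd_diam_add_um),
    diam_scale = stats::rnorm(spec$n_samples, 1, spec$sd_diam_scale),
    F = pmax(1, stats::rnorm(spec$n_samples, config$F, spec$sd_F)),
    start_um = pmax(0, stats::rnorm(spec$n_samples, config$spine_start_um,
                                    spec$sd_start_um))))
  vals <- matrix(NA_real_, spec$n_samples, 3,
                 dimnames = list(NULL, c("cm", "rm", "ra")))
  n_clipped <- 0L
  for (i in seq_len(spec$n_samples)) {
    pm <- perturb_morphology(morph, draws$length_scale[i], draws$diam_add[i],
                             draws$diam_scale[i], spec$min_diam_um)
    n_clipped <- n_clipped + attr(pm, "n_clipped")
    cfg <- config
    cfg$F <- draws$F[i]
    cfg$spine_start_um <- draws$start_um[i]
    ss1 <- sweep_set(avg$time_ms, matrix(avg$v_mV, ncol = 1), avg$amp_pA,
                     avg$delay_ms, avg$dur_ms)
    fr <- tryCatch(fit_passive(pm, ss1, cfg, start = start),
                   error = function(e) NULL)
    if (!is.null(fr)) vals[i, ] <- c(fr$params$cm, fr$params$rm, fr$params$ra)
  }
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  means <- colMeans(vals, na.rm = TRUE)
  list(fit = fit, sd = sds, sd_rel_pct = 100 * sds / means,
       samples = cbind(draws, as.data.frame(vals)), n_clipped = n_clipped)
}

## run an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
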