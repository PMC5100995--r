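## Passive-parameter inference: averaged transients, the RMSD objective,
## multi-start derivative-free fitting, constrained profiles, Ih variants.

#' A set of repeated voltage sweeps for one stimulus
#'
#' @param time_ms shared time grid, ms (uniform).
#' @param v_mV matrix of sweeps, one column per repetition.
#' @param amp_pA stimulus amplitude, pA (signed).
#' @param delay_ms,dur_ms pulse onset and duration, ms.
#' @param junction_mV liquid junction potential subtracted from the
#'   recorded absolute potentials (affects the reported resting level
#'   only; transient fitting uses baseline-subtracted deflections).
#' @return object of class `sweep_set`.
#' @export
sweep_set <- function(time_ms, v_mV, amp_pA, delay_ms = 10, dur_ms = 2,
                      junction_mV = 0) {
  v_mV <- as.matrix(v_mV)
  if (nrow(v_mV) != length(time_ms)) stop("sweep grid mismatch")
  if (ncol(v_mV) < 1L) stop("sweep set needs at least one sweep")
  if (any(diff(time_ms) <= 0)) stop("time grid must be strictly increasing")
  structure(list(time_ms = time_ms, v_mV = v_mV, amp_pA = amp_pA,
                 delay_ms = delay_ms, dur_ms = dur_ms,
                 junction_mV = junction_mV), class = "sweep_set")
}

#' Average a sweep set into a single transient
#'
#' Pointwise mean over sweeps, pre-stimulus baseline subtracted. The
#' absolute resting potential (baseline minus junction correction) is
#' retained as an attribute.
#'
#' @param ss a [sweep_set()], or a plain matrix plus stimulus metadata via
#'   the other arguments of [sweep_set()].
#' @return list with `time_ms`, `v_mV` (baseline-subtracted mean),
#'   stimulus fields, and `rest_mV`.
#' @export
average_transient <- function(ss) {
  stopifnot(inherits(ss, "sweep_set"))
  m <- rowMeans(ss$v_mV)
  pre <- ss$time_ms < ss$delay_ms
  if (!any(pre)) pre <- seq_len(max(1L, floor(length(m) * 0.02)))
  baseline <- mean(m[pre])
  list(time_ms = ss$time_ms, v_mV = m - baseline,
       amp_pA = ss$amp_pA, delay_ms = ss$delay_ms, dur_ms = ss$dur_ms,
       rest_mV = baseline - ss$junction_mV)
}

#' Root-mean-square deviation between two transients on a window
#'
#' @param model,target lists with `time_ms` and `v_mV` on a common grid
#'   (model may be on a finer grid containing the target's samples).
#' @param window_ms `c(t1, t2)` in absolute trace time; only samples in
#'   the window enter the deviation.
#' @return RMSD in mV.
#' @export
rmsd <- function(model, target, window_ms) {
  sel <- target$time_ms >= window_ms[1] & target$time_ms <= window_ms[2]
  if (!any(sel)) stop("empty RMSD window")
  mv <- if (is.matrix(model$v_mV)) model$v_mV[, 1] else model$v_mV
  if (length(mv) != length(target$time_ms)) {
    idx <- match(round(target$time_ms, 6), round(model$time_ms, 6))
    if (anyNA(idx)) stop("model grid does not contain the target samples")
    mv <- mv[idx]
  }
  tv <- if (is.matrix(target$v_mV)) target$v_mV[, 1] else target$v_mV
  sqrt(mean((mv[sel] - tv[sel])^2))
}

#' Fitting configuration
#'
#' @param bounds list of `c(lo, hi)` for `cm` (uF/cm^2), `rm` (Ohm cm^2),
#'   `ra` (Ohm cm); optimisation runs in log-space within these boxes.
#' @param n_starts multi-start count (Latin-hypercube initial points).
#' @param window_ms RMSD window relative to the pulse, ms.
#' @param window_from `"offset"` (window counted from the end of the
#'   pulse, the default) or `"onset"`.
#' @param dt solver time step for model transients, ms (model responses
#'   are sampled onto the data grid, so the data dt must be an integer
#'   multiple of `dt`).
#' @param rule discretization rule ([dx_rule()]).
#' @param F,spine_start_um global spine correction
#'   ([apply_spine_correction()]).
#' @param maxit,reltol Nelder-Mead control per start.
#' @param seed RNG seed controlling the multi-start draw.
#' @export
fit_config <- function(bounds = list(cm = c(0.2, 2), rm = c(5e3, 1e5),
                                     ra = c(50, 400)),
                       n_starts = 5, window_ms = c(1, 100),
                       window_from = c("offset", "onset"), dt = 0.05,
                       rule = dx_rule(), F = 1.9, spine_start_um = 60,
                       maxit = 400, reltol = 1e-9, seed = 1) {
  window_from <- match.arg(window_from)
  stopifnot(all(unlist(bounds) > 0), n_starts >= 1)
  structure(list(bounds = bounds, n_starts = n_starts, window_ms = window_ms,
                 window_from = window_from, dt = dt, rule = rule, F = F,
                 spine_start_um = spine_start_um, maxit = maxit,
                 reltol = reltol, seed = seed), class = "fit_config")
}

fit_window <- function(avg, config) {
  origin <- avg$delay_ms + if (config$window_from == "offset") avg$dur_ms else 0
  w <- origin + config$window_ms
  w[2] <- min(w[2], max(avg$time_ms))
  w
}

## simulate the model deflection for one stimulus on the data grid
## (passive system is linear, so E_pas = 0 and the response is the
## deflection directly); cache-friendly: comps fixed, params vary
model_transient <- function(comps, cm, rm, ra, avg, config,
                            ih = NULL, e_pas = -70) {
  passive <- passive_params(cm = cm, rm = rm, ra = ra,
                            e_pas = if (is.null(ih)) 0 else e_pas)
  cable <- build_cable(comps, passive, ih = ih)
  sub <- max(1L, round(stats::median(diff(avg$time_ms)) / config$dt))
  dt <- stats::median(diff(avg$time_ms)) / sub
  tr <- simulate(cable,
                 current_step(avg$amp_pA / 1000, avg$delay_ms, avg$dur_ms),
                 dt = dt, t_stop = max(avg$time_ms),
                 settle_ms = if (is.null(ih)) 0 else 200)
  v <- tr$v_mV[, 1]
  if (!is.null(ih)) {
    base <- mean(v[tr$time_ms < avg$delay_ms])
    v <- v - base
  }
  list(time_ms = tr$time_ms, v_mV = v)
}

log_bounds <- function(bounds)
  list(lo = log(c(bounds$cm[1], bounds$rm[1], bounds$ra[1])),
       hi = log(c(bounds$cm[2], bounds$rm[2], bounds$ra[2])))

#' Fit passive cable parameters to averaged voltage transients
#'
#' Minimises the RMSD between the averaged experimental transient and the
#' model response over (Cm, Rm, Ra), in log-space, by Nelder-Mead from
#' `n_starts` Latin-hypercube starting points within the bounds. The fit
#' uses one stimulus (the strongest depolarizing pulse by default, per
#' the standard protocol) and validates the result on the remaining
#' amplitudes. Deterministic for a given `config$seed`.
#'
#' @param morph a [morphology()] object (the spine correction from
#'   `config` is applied to its discretization).
#' @param sweeps a [sweep_set()] or list of sweep sets (one per stimulus
#'   amplitude).
#' @param config a [fit_config()].
#' @param fixed optional named list fixing a subset of
#'   `c("cm", "rm", "ra")` at given values (used for profiles).
#' @param ih optional [ih_distribution()] held fixed during the fit.
#' @param start optional named vector `c(cm, rm, ra)` used as the single
#'   warm start (replaces the multi-start).
#' @return object of class `fit_result`: `params` ([passive_params()]),
#'   `rmsd_mV`, `window_ms`, `validation` (per-stimulus RMSDs),
#'   `starts` (per-start outcomes), `converged`.
#' @export
fit_passive <- function(morph, sweeps, config = fit_config(), fixed = list(),
                        ih = NULL, start = NULL) {
  if (inherits(sweeps, "sweep_set")) sweeps <- list(sweeps)
  comps <- apply_spine_correction(discretize(morph, config$rule),
                                  config$F, config$spine_start_um)
  avgs <- lapply(sweeps, average_transient)
  amps <- vapply(avgs, function(a) a$amp_pA, numeric(1))
  fit_i <- if (any(amps > 0)) which.max(amps) else which.min(amps)
  avg <- avgs[[fit_i]]
  window <- fit_window(avg, config)

  free <- setdiff(c("cm", "rm", "ra"), names(fixed))
  lb <- log_bounds(config$bounds)
  names(lb$lo) <- names(lb$hi) <- c("cm", "rm", "ra")

  objective <- function(logp_free) {
    p <- exp(logp_free)
    names(p) <- free
    full <- c(as.list(p), fixed)
    pen <- 0
    for (nm in free) {
      b <- config$bounds[[nm]]
      if (full[[nm]] < b[1]) { pen <- pen + (log(b[1] / full[[nm]]))^2
                               full[[nm]] <- b[1] }
      if (full[[nm]] > b[2]) { pen <- pen + (log(full[[nm]] / b[2]))^2
                               full[[nm]] <- b[2] }
    }
    mt <- model_transient(comps, full$cm, full$rm, full$ra, avg, config,
                          ih = ih)
    rmsd(mt, avg, window) * (1 + pen) + pen
  }

  if (!is.null(start)) {
    starts <- matrix(log(start[free]), nrow = 1)
  } else {
    set.seed(config$seed)
    k <- length(free)
    u <- rbind(rep(0.5, k),
               if (config$n_starts > 1) lhs::randomLHS(config$n_starts - 1, k))
    starts <- sweep(sweep(u, 2, lb$hi[free] - lb$lo[free], "*"),
                    2, lb$lo[free], "+")
  }

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = config$reltol))
    runs[[i]] <- list(par = exp(opt$par), value = opt$value,
                      convergence = opt$convergence)
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  cms <- vapply(runs, function(r)
    if ("cm" %in% free) r$par[match("cm", free)] else fixed$cm, numeric(1))
  best_i <- order(vals, cms)[1]      # tie-break: lowest RMSD, then lowest Cm
  best <- runs[[best_i]]
  ## polish the winner
  opt <- stats::optim(log(best$par), objective, method = "Nelder-Mead",
                      control = list(maxit = config$maxit,
                                     reltol = config$reltol))
  best <- list(par = exp(opt$par), value = opt$value,
               convergence = opt$convergence)

  p <- best$par; names(p) <- free
  full <- c(as.list(p), fixed)
  params <- passive_params(cm = full$cm, rm = full$rm, ra = full$ra,
                           e_pas = avg$rest_mV)

  validation <- data.frame(amp_pA = amps, rmsd_mV = NA_real_,
                           fitted = seq_along(amps) == fit_i)
  for (j in seq_along(avgs)) {
    mt <- model_transient(comps, full$cm, full$rm, full$ra, avgs[[j]],
                          config, ih = ih)
    validation$rmsd_mV[j] <- rmsd(mt, avgs[[j]], fit_window(avgs[[j]], config))
  }

  structure(list(params = params, rmsd_mV = best$value, window_ms = window,
                 validation = validation,
                 starts = data.frame(
                   value = vals,
                   convergence = vapply(runs, `[[`, numeric(1), "convergence")),
                 converged = best$convergence == 0 || best$value < min(vals),
                 fixed = fixed, ih = ih), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("fit_result: Cm = %.3f uF/cm^2, Rm = %.0f Ohm cm^2, Ra = %.0f Ohm cm\n",
              p$cm, p$rm, p$ra))
  cat(sprintf("RMSD = %.4f mV on window [%.1f, %.1f] ms\n",
              x$rmsd_mV, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Constrained-parameter RMSD profile
#'
#' Fixes one passive parameter at each grid value, re-optimises the other
#' two, and records the best RMSD: the profile's curvature around its
#' minimum measures how well the data constrain that parameter (sharp for
#' Cm, shallow for Ra).
#'
#' @param morph,sweeps,config as [fit_passive()].
#' @param param one of `"cm"`, `"rm"`, `"ra"`.
#' @param grid values at which to constrain `param`.
#' @param warm_start optional `c(cm, rm, ra)` used to warm-start every
#'   grid point (e.g. the unconstrained best fit).
#' @return data frame `value`, `rmsd_mV`.
#' @export
profile_constrained <- function(morph, sweeps, param, grid,
                                config = fit_config(), warm_start = NULL) {
  stopifnot(param %in% c("cm", "rm", "ra"))
  out <- data.frame(value = grid, rmsd_mV = NA_real_)
  for (i in seq_along(grid)) {
    fixed <- stats::setNames(list(grid[i]), param)
    st <- if (is.null(warm_start)) NULL else
      warm_start[setdiff(c("cm", "rm", "ra"), param)]
    fr <- fit_passive(morph, sweeps, config, fixed = fixed, start = st)
    out$rmsd_mV[i] <- fr$rmsd_mV
  }
  out
}

#' Fit passive parameters with a fixed Ih distribution
#'
#' As [fit_passive()] but with hyperpolarization-activated current of
#' somatic density `g_soma` (flat in basal dendrites, growing with
#' distance in the apical tree) present and held fixed while (Cm, Rm, Ra)
#' are optimised. Reports the residual over the first few milliseconds
#' after the pulse separately: at short times the transient is dominated
#' by the capacitive current, so the early residual isolates the Cm
#' estimate from slow conductances.
#'
#' @param morph,sweeps,config,fixed as [fit_passive()].
#' @param g_soma somatic Ih density, mS/cm^2 (0 reduces exactly to the
#'   passive fit).
#' @param early_ms length of the early residual window after pulse
#'   offset, ms.
#' @return a `fit_result` with extra fields `early_rmsd_mV` and `g_soma`.
#' @export
fit_with_ih <- function(morph, sweeps, g_soma = 0, config = fit_config(),
                        fixed = list(), early_ms = 3) {
  ih <- if (g_soma > 0) ih_distribution(g_soma) else NULL
  fr <- fit_passive(morph, sweeps, config, fixed = fixed, ih = ih)
  ## early-window residual on the fitted stimulus
  if (inherits(sweeps, "sweep_set")) sweeps <- list(sweeps)
  avgs <- lapply(sweeps, average_transient)
  amps <- vapply(avgs, function(a) a$amp_pA, numeric(1))
  avg <- avgs[[if (any(amps > 0)) which.max(amps) else which.min(amps)]]
  comps <- apply_spine_correction(discretize(morph, config$rule),
                                  config$F, config$spine_start_um)
  p <- fr$params
  mt <- model_transient(comps, p$cm, p$rm, p$ra, avg, config, ih = ih)
  early <- avg$delay_ms + avg$dur_ms + c(0, early_ms)
  fr$early_rmsd_mV <- rmsd(mt, avg, early)
  fr$g_soma <- g_soma
  fr
}
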