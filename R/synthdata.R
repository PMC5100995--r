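## Synthetic fixtures: morphologies, ground-truth transient sweep sets
## with per-sweep noise, and series-RC nucleated-patch recordings.

#' Specification for synthetic data generation
#'
#' The defaults emulate the human L2/3 recording conditions: dendritic
#' trees with maximal path distance drawn near 1050 +/- 178 um, six
#' stimulus amplitudes (+/-50, +/-100, +/-200 pA; 2 ms pulses), 50 sweeps
#' per stimulus, and additive per-sample Gaussian sweep noise of 0.2 mV.
#'
#' @param kind `"ball_and_stick"` (soma sphere, one apical cylinder, two
#'   basal cylinders) or `"random_tree"` (branched apical + basal domains).
#' @param target_path_um target maximal dendritic path distance, um;
#'   `NULL` draws from N(1050, 178).
#' @param truth ground-truth [passive_params()].
#' @param F,spine_start_um ground-truth spine correction.
#' @param stim_amps_pA stimulus amplitudes, pA.
#' @param delay_ms,dur_ms pulse timing, ms.
#' @param t_stop_ms sweep length, ms.
#' @param data_dt_ms sampling interval of the sweeps, ms.
#' @param noise_sd_mV per-sample, per-sweep Gaussian noise SD, mV.
#' @param n_sweeps repetitions per stimulus.
#' @param rest_mV resting potential added to the sweeps, mV.
#' @param seed RNG seed (mandatory for stochastic kinds).
#' @export
synthetic_spec <- function(kind = c("ball_and_stick", "random_tree"),
                           target_path_um = NULL,
                           truth = passive_params(cm = 0.5, rm = 40000,
                                                  ra = 200),
                           F = 1.9, spine_start_um = 60,
                           stim_amps_pA = c(-200, -100, -50, 50, 100, 200),
                           delay_ms = 10, dur_ms = 2, t_stop_ms = 115,
                           data_dt_ms = 0.1, noise_sd_mV = 0.2,
                           n_sweeps = 50, rest_mV = -70, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_sweeps >= 1, noise_sd_mV >= 0, data_dt_ms > 0)
  structure(list(kind = kind, target_path_um = target_path_um, truth = truth,
                 F = F, spine_start_um = spine_start_um,
                 stim_amps_pA = stim_amps_pA, delay_ms = delay_ms,
                 dur_ms = dur_ms, t_stop_ms = t_stop_ms,
                 data_dt_ms = data_dt_ms, noise_sd_mV = noise_sd_mV,
                 n_sweeps = n_sweeps, rest_mV = rest_mV, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic morphology
#'
#' `ball_and_stick`: soma sphere (20 um) with a 400 um apical cylinder
#' (2 um) and two 150 um basal cylinders (1 um). `random_tree`: an apical
#' trunk with a recursively branching tuft plus several branched basal
#' subtrees, tapering diameters; the maximal dendritic path distance lands
#' within 10% of `target_path_um`. Pure function of (spec, seed).
#'
#' @param spec a [synthetic_spec()].
#' @param path optional file path; when given the morphology is also
#'   written as SWC.
#' @return a [morphology()] object.
#' @export
gen_morphology <- function(spec = synthetic_spec(), path = NULL) {
  m <- with_seed(spec$seed, {
    if (spec$kind == "ball_and_stick") gen_ball_and_stick()
    else {
      target <- spec$target_path_um
      if (is.null(target)) target <- stats::rnorm(1, 1050, 178)
      gen_random_tree(target)
    }
  })
  if (!is.null(path)) write_swc(m, path)
  m
}

gen_ball_and_stick <- function(soma_diam = 20, stick_len = 400,
                               stick_diam = 2, basal_len = 150,
                               basal_diam = 1) {
  soma <- section(1, "soma", matrix(c(0, 0, 0, soma_diam), 1))
  ap <- section(2, "apical", rbind(c(0, 0, 0, stick_diam),
                                   c(0, 0, stick_len, stick_diam)),
                parent = 1)
  b1 <- section(3, "basal", rbind(c(0, 0, 0, basal_diam),
                                  c(0, basal_len, 0, basal_diam)),
                parent = 1)
  b2 <- section(4, "basal", rbind(c(0, 0, 0, basal_diam),
                                  c(0, -basal_len, 0, basal_diam)),
                parent = 1)
  morphology(list(soma, ap, b1, b2), metadata = "synthetic ball-and-stick")
}

## recursive binary tree with tapering diameters; the main apical path is
## constructed to the exact target length, side paths are jittered shorter
gen_random_tree <- function(target_path_um, soma_diam = 16) {
  secs <- list()
  next_id <- 1L
  new_sec <- function(kind, p0, p1, d0, d1, parent) {
    id <- next_id
    secs[[id]] <<- section(id, kind, rbind(c(p0, d0), c(p1, d1)),
                           parent = parent)
    next_id <<- next_id + 1L
    id
  }
  soma <- new_sec("soma", c(0, 0, 0), c(0, 0, 0), soma_diam, soma_diam, NA)
  secs[[soma]] <- section(soma, "soma", matrix(c(0, 0, 0, soma_diam), 1))

  ## apical: trunk (45% of target) then a tuft bifurcation cascade
  trunk_len <- 0.45 * target_path_um
  trunk <- new_sec("apical", c(0, 0, 0), c(0, 0, trunk_len), 2.6, 1.6, soma)
  grow <- function(kind, parent, base, dirv, remaining, diam, depth) {
    if (remaining < 40 || depth > 4) return(invisible())
    len_main <- if (depth >= 3) remaining else remaining * stats::runif(1, 0.45, 0.6)
    ang <- stats::runif(1, -0.5, 0.5)
    d1 <- c(dirv[1] * cos(ang) - dirv[2] * sin(ang),
            dirv[1] * sin(ang) + dirv[2] * cos(ang), dirv[3])
    d1 <- d1 / sqrt(sum(d1^2))
    tip <- base + d1 * len_main
    id <- new_sec(kind, base, tip, diam, max(0.4, diam * 0.7), parent)
    ## main child continues toward the target, a shorter sibling branches off
    grow(kind, id, tip, d1, remaining - len_main, max(0.4, diam * 0.7),
         depth + 1)
    side_len <- (remaining - len_main) * stats::runif(1, 0.4, 0.8)
    if (side_len > 40) {
      d2 <- c(-d1[2], d1[1], d1[3]); d2 <- d2 / sqrt(sum(d2^2))
      sid <- new_sec(kind, tip, tip + d2 * side_len, max(0.4, diam * 0.7),
                     0.4, id)
      grow(kind, sid, tip + d2 * side_len, d2, side_len * 0.5, 0.4, depth + 2)
    }
    invisible()
  }
  grow("apical", trunk, c(0, 0, trunk_len), c(0, 0, 1),
       0.55 * target_path_um, 1.4, 1)
  ## basal subtrees, ~25-35% of target each
  nb <- 4L
  for (b in seq_len(nb)) {
    ang <- 2 * pi * (b - 0.5) / nb
    dirv <- c(cos(ang), sin(ang), -0.3)
    dirv <- dirv / sqrt(sum(dirv^2))
    blen <- target_path_um * stats::runif(1, 0.22, 0.32)
    st <- new_sec("basal", c(0, 0, 0), dirv * blen * 0.5, 1.1, 0.8, soma)
    tip <- dirv * blen * 0.5
    for (k in 1:2) {
      d2 <- dirv + c(stats::runif(1, -0.4, 0.4), stats::runif(1, -0.4, 0.4), 0)
      d2 <- d2 / sqrt(sum(d2^2))
      new_sec("basal", tip, tip + d2 * blen * 0.5, 0.8, 0.5, st)
    }
  }
  morphology(secs, metadata = sprintf("synthetic random tree (target %.0f um)",
                                      target_path_um))
}

#' Generate ground-truth transient sweep sets
#'
#' Simulates the noiseless response of `morph` at the spec's ground-truth
#' passive parameters (with the spine correction applied) for every
#' stimulus amplitude, then adds iid Gaussian noise per sweep sample.
#' Pure function of (morph, spec).
#'
#' @param morph a [morphology()] object.
#' @param spec a [synthetic_spec()].
#' @param rule discretization rule for the ground-truth simulation.
#' @return list of [sweep_set()] objects, one per amplitude, with the
#'   ground truth attached as attribute `"truth"`.
#' @export
gen_transients <- function(morph, spec = synthetic_spec(),
                           rule = dx_rule()) {
  comps <- apply_spine_correction(discretize(morph, rule), spec$F,
                                  spec$spine_start_um)
  truth <- spec$truth
  cable <- build_cable(comps,
                       passive_params(truth$cm, truth$rm, truth$ra, e_pas = 0))
  nt <- round(spec$t_stop_ms / spec$data_dt_ms)
  sub <- 2L   # model step = half the data sampling interval
  dt <- spec$data_dt_ms / sub
  out <- with_seed(spec$seed, lapply(spec$stim_amps_pA, function(amp) {
    tr <- simulate(cable, current_step(amp / 1000, spec$delay_ms,
                                       spec$dur_ms),
                   dt = dt, t_stop = spec$t_stop_ms)
    keep <- seq(1, length(tr$time_ms), by = sub)
    clean <- tr$v_mV[keep, 1] + spec$rest_mV
    sweeps <- matrix(clean, nrow = length(keep), ncol = spec$n_sweeps) +
      if (spec$noise_sd_mV > 0)
        stats::rnorm(length(keep) * spec$n_sweeps, 0, spec$noise_sd_mV)
      else 0
    sweep_set(tr$time_ms[keep], sweeps, amp, spec$delay_ms, spec$dur_ms)
  }))
  attr(out, "truth") <- list(cm = truth$cm, rm = truth$rm, ra = truth$ra,
                             F = spec$F, spine_start_um = spec$spine_start_um)
  out
}

#' Generate a synthetic nucleated-patch recording
#'
#' Ideal series-RC capacitive transient `I(t) = (dV/Rs) exp(-t/tau)` with
#' `tau = Rs C`, optional residual (sealed-pipette) transient, and
#' proportional Gaussian noise.
#'
#' @param c_pF patch capacitance, pF.
#' @param rs_MOhm series resistance, MOhm.
#' @param major_um,minor_um patch axes, um.
#' @param dv_mV step amplitude, mV.
#' @param noise_frac noise SD as a fraction of the peak current.
#' @param r_in_MOhm input resistance recorded with the patch, MOhm.
#' @param with_residual add a small fast pipette transient (and supply it
#'   as the residual control trace)?
#' @param dt_ms sampling interval, ms (default 0.004 = 250 kHz).
#' @param t_stop_ms trace length, ms.
#' @param seed RNG seed.
#' @return a [patch_recording()] with the truth attached as attribute
#'   `"truth"`.
#' @export
gen_patch <- function(c_pF = 2, rs_MOhm = 10, major_um = 11.3, minor_um = 10.5,
                      dv_mV = -5, noise_frac = 0, r_in_MOhm = 500,
                      with_residual = FALSE, dt_ms = 0.004, t_stop_ms = 3,
                      seed = 1) {
  stopifnot(c_pF > 0, rs_MOhm > 0)
  time <- seq(0, t_stop_ms, by = dt_ms)
  step_ms <- 1
  tau <- rs_MOhm * c_pF * 1e-3                 # MOhm pF -> ms
  i0 <- dv_mV / rs_MOhm * 1000                 # mV / MOhm -> pA
  tt <- pmax(0, time - step_ms)
  i <- ifelse(time >= step_ms, i0 * exp(-tt / tau), 0)
  residual <- NULL
  if (with_residual) {
    c_res <- 0.15; tau_res <- 0.008
    ir0 <- dv_mV / (tau_res / c_res * 1e3) * 1000
    residual <- ifelse(time >= step_ms, ir0 * exp(-tt / tau_res), 0)
    i <- i + residual
  }
  if (noise_frac > 0)
    i <- i + with_seed(seed, stats::rnorm(length(i), 0, noise_frac * abs(i0)))
  rec <- patch_recording(time, i, dv_mV, step_ms, major_um, minor_um,
                         r_in_MOhm, residual_pA = residual)
  attr(rec, "truth") <- list(c_pF = c_pF, tau_ms = tau,
                             area_um2 = ellipse_area(major_um, minor_um),
                             cm_uF_cm2 = specific_cm(c_pF,
                               ellipse_area(major_um, minor_um)))
  rec
}

#' Write sweep sets to CSV files
#'
#' One CSV per stimulus (`time_ms` column plus one column per sweep) and a
#' YAML sidecar holding the stimulus metadata (the ground truth is kept
#' out of the data files so fits can be blinded).
#'
#' @param sweeps list of [sweep_set()] objects.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sweeps <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (i in seq_along(sweeps)) {
    ss <- sweeps[[i]]
    f <- sprintf("sweeps_%+dpA.csv", as.integer(ss$amp_pA))
    df <- data.frame(time_ms = ss$time_ms, ss$v_mV)
    names(df) <- c("time_ms", paste0("sweep", seq_len(ncol(ss$v_mV))))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    meta[[i]] <- list(file = f, amp_pA = ss$amp_pA, delay_ms = ss$delay_ms,
                      dur_ms = ss$dur_ms, junction_mV = ss$junction_mV)
  }
  yaml::write_yaml(meta, file.path(dir, "sweeps.yaml"))
  invisible(dir)
}

#' Read sweep sets written by [write_sweeps()]
#' @param dir directory containing `sweeps.yaml` and the CSV files.
#' @return list of [sweep_set()] objects.
#' @export
read_sweeps <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "sweeps.yaml"))
  lapply(meta, function(m) {
    df <- utils::read.csv(file.path(dir, m$file))
    sweep_set(df$time_ms, as.matrix(df[, -1, drop = FALSE]), m$amp_pA,
              m$delay_ms, m$dur_ms, m$junction_mV)
  })
}
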