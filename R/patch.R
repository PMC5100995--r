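## Nucleated-patch capacitance estimation: surface area from patch axes,
## mono-exponential fit of the capacitive current, QC.

#' Nucleated-patch recording container
#'
#' @param time_ms time grid, ms.
#' @param i_pA averaged capacitive current, pA.
#' @param dv_mV voltage-clamp step amplitude, mV (-5 in the standard
#'   protocol; must be non-zero).
#' @param step_ms time of step onset, ms.
#' @param major_um,minor_um major and minor axis of the (approximately
#'   ellipsoidal) patch, um.
#' @param r_in_MOhm input resistance, MOhm (`NA` if not measured).
#' @param residual_pA optional residual (sealed-pipette control) trace on
#'   the same grid, to be subtracted before fitting.
#' @export
patch_recording <- function(time_ms, i_pA, dv_mV = -5, step_ms = 1,
                            major_um = NA, minor_um = NA, r_in_MOhm = NA,
                            residual_pA = NULL) {
  if (dv_mV == 0) stop("step amplitude must be non-zero")
  if (!is.na(major_um) && major_um <= 0) stop("axes must be positive")
  if (!is.na(minor_um) && minor_um <= 0) stop("axes must be positive")
  structure(list(time_ms = time_ms, i_pA = i_pA, dv_mV = dv_mV,
                 step_ms = step_ms, major_um = major_um, minor_um = minor_um,
                 r_in_MOhm = r_in_MOhm, residual_pA = residual_pA),
            class = "patch_recording")
}

#' Patch surface area from its axes
#'
#' `area = (major + minor)^2 * pi/4`: the sphere surface formula applied
#' to the mean of the two axes.
#'
#' @param major_um,minor_um axes, um.
#' @return area in um^2.
#' @export
ellipse_area <- function(major_um, minor_um) {
  if (any(major_um <= 0) || any(minor_um <= 0))
    stop("patch axes must be positive")
  (major_um + minor_um)^2 * pi / 4
}

#' Fit a mono-exponential to the capacitive transient
#'
#' Subtracts the pre-step baseline (and the residual control trace, if
#' present), fits `I(t) = I0 exp(-(t - t_on)/tau)` from `skip_samples`
#' after step onset, and converts charge to capacitance:
#' `C = I0 * tau / |dV|` (pA ms / mV = pF). When a residual trace is
#' supplied both the raw and residual-subtracted estimates are reported.
#'
#' @param rec a [patch_recording()].
#' @param skip_samples samples skipped after onset (clamp settling).
#' @param fit_ms length of the fit window, ms.
#' @param r2_min QC threshold on the fit R^2.
#' @return object of class `patch_result`: `tau_ms`, `i0_pA`,
#'   `c_total_pF`, `c_total_raw_pF` (no residual subtraction),
#'   `area_um2`, `cm_uF_cm2`, `r2`, `qc` flags.
#' @export
fit_capacitive_transient <- function(rec, skip_samples = 2, fit_ms = 2,
                                     r2_min = 0.8) {
  stopifnot(inherits(rec, "patch_recording"))
  fit_one <- function(i_pA) {
    pre <- rec$time_ms < rec$step_ms
    base <- if (any(pre)) mean(i_pA[pre]) else 0
    y <- i_pA - base
    dt <- stats::median(diff(rec$time_ms))
    t0 <- rec$step_ms + skip_samples * dt
    sel <- rec$time_ms >= t0 & rec$time_ms <= rec$step_ms + fit_ms
    ts <- rec$time_ms[sel] - rec$step_ms
    ys <- y[sel]
    sgn <- sign(ys[1])
    if (sgn == 0 || stats::sd(ys) == 0) stop("no transient to fit")
    ## log-linear start over the top decade-and-a-bit of the decay (the
    ## noisy tail would bias the slope), then bounded nonlinear refinement
    pos <- sgn * ys > max(sgn * ys) * 0.05
    if (sum(pos) < 3) pos <- seq_len(min(5, length(ys)))
    lf <- stats::lm(log(pmax(sgn * ys[pos], max(sgn * ys) * 1e-6)) ~ ts[pos])
    tau0 <- unname(-1 / stats::coef(lf)[2])
    if (!is.finite(tau0) || tau0 <= 0) stop("transient does not decay")
    i00 <- unname(sgn * exp(stats::coef(lf)[1]))
    ## refine over ~8 time constants: a long all-noise tail would otherwise
    ## dominate the least-squares fit of a fast transient
    keep <- ts <= max(8 * tau0, 12 * dt)
    df <- data.frame(ts = ts[keep], ys = ys[keep])
    span <- max(ts)
    nl <- minpack.lm::nlsLM(ys ~ i0 * exp(-ts / tau), data = df,
                            start = list(i0 = i00,
                                         tau = min(max(tau0, dt), span)),
                            lower = c(i0 = -10 * max(abs(ys)), tau = dt / 4),
                            upper = c(i0 = 10 * max(abs(ys)), tau = 2 * span))
    cf <- stats::coef(nl)
    ss_res <- sum(stats::resid(nl)^2)
    ss_tot <- sum((ys - mean(ys))^2)
    list(tau = unname(cf["tau"]), i0 = unname(cf["i0"]),
         r2 = 1 - ss_res / ss_tot)
  }
  raw <- fit_one(rec$i_pA)
  sub <- if (!is.null(rec$residual_pA)) fit_one(rec$i_pA - rec$residual_pA)
         else raw
  c_of <- function(f) abs(f$i0) * f$tau / abs(rec$dv_mV)   # pF
  area <- if (!is.na(rec$major_um) && !is.na(rec$minor_um))
    ellipse_area(rec$major_um, rec$minor_um) else NA_real_
  c_tot <- c_of(sub)
  structure(list(tau_ms = sub$tau, i0_pA = sub$i0, c_total_pF = c_tot,
                 c_total_raw_pF = c_of(raw), area_um2 = area,
                 cm_uF_cm2 = if (is.na(area)) NA_real_
                             else specific_cm(c_tot, area),
                 r2 = sub$r2,
                 qc = list(r2_ok = sub$r2 >= r2_min,
                           r_in = qc_filter(rec))),
            class = "patch_result")
}

#' Specific membrane capacitance from total capacitance and area
#'
#' @param c_total_pF total capacitance, pF.
#' @param area_um2 membrane area, um^2.
#' @return specific capacitance in uF/cm^2 (pF/um^2 x 100).
#' @export
specific_cm <- function(c_total_pF, area_um2) {
  stopifnot(all(area_um2 > 0))
  100 * c_total_pF / area_um2
}

#' Input-resistance quality control
#'
#' Patches with input resistance below 200 MOhm are excluded; the
#' threshold itself passes.
#'
#' @param rec a [patch_recording()] (or a bare resistance in MOhm).
#' @param min_MOhm exclusion threshold.
#' @return `"pass"`, `"fail"`, or `"indeterminate"` when R_in is missing.
#' @export
qc_filter <- function(rec, min_MOhm = 200) {
  r <- if (inherits(rec, "patch_recording")) rec$r_in_MOhm else rec
  if (is.na(r)) return("indeterminate")
  if (r < min_MOhm) "fail" else "pass"
}
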