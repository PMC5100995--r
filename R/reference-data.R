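#' Reference passive-parameter fits for six human L2/3 pyramidal cells
#'
#' Published best-fit passive cable parameters, with balanced-bootstrap
#' statistical and morphology-perturbation systematic standard deviations,
#' obtained by transient fitting of six 3D-reconstructed human temporal
#' cortex layer 2/3 pyramidal neurons. Useful as a reference point for
#' synthetic studies (e.g. the implied membrane time constants
#' `tau_m = Rm Cm`) and for choosing realistic ground-truth values.
#'
#' Columns: `cell` (recording identifier), `cm_uF_cm2`, `cm_sd_stat`,
#' `cm_sd_sys`, `rm_kOhm_cm2`, `rm_sd_stat`, `rm_sd_sys`, `ra_Ohm_cm`,
#' `ra_sd_stat`, `ra_sd_sys`.
#'
#' @export
hl23_reference_fits <- data.frame(
  cell = c("060303", "060308", "060311", "130303", "130305", "130306"),
  cm_uF_cm2 = c(0.488, 0.452, 0.441, 0.430, 0.497, 0.520),
  cm_sd_stat = c(0.045, 0.026, 0.248, 0.034, 0.027, 0.0219),
  cm_sd_sys = c(0.183, 0.196, 0.257, 0.158, 0.207, 0.236),
  rm_kOhm_cm2 = c(21.41, 38.91, 48.73, 35.67, 31.31, 36.52),
  rm_sd_stat = c(1.21, 1.65, 22.90, 7.40, 1.99, 2.89),
  rm_sd_sys = c(6.57, 13.29, 14.96, 11.62, 8.96, 11.51),
  ra_Ohm_cm = c(281.78, 203.23, 261.97, 274.44, 292.95, 290.28),
  ra_sd_stat = c(34.12, 29.31, 179.31, 32.24, 59.04, 15.41),
  ra_sd_sys = c(152.05, 96.18, 27.22, 171.63, 164.46, 137.46),
  stringsAsFactors = FALSE)
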