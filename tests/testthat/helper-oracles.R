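## Shared fixtures and independent analytic oracles.

make_soma_only <- function(diam = 20) {
  morphology(list(section(1, "soma", matrix(c(0, 0, 0, diam), 1))))
}

make_ball_stick <- function(soma_diam = 20, stick_diam = 2, stick_len = 600) {
  soma <- section(1, "soma", matrix(c(0, 0, 0, soma_diam), 1))
  ap <- section(2, "apical", rbind(c(0, 0, 0, stick_diam),
                                   c(0, 0, stick_len, stick_diam)),
                parent = 1)
  morphology(list(soma, ap))
}

## Analytic somatic response of an isopotential sphere to a current step
## (simple RC): V(t) = I R (1 - exp(-t/tau)), relative to rest.
rc_step_mV <- function(t_ms, i_nA, diam_um, cm, rm) {
  area_cm2 <- pi * diam_um^2 * 1e-8
  R <- rm / area_cm2                       # Ohm
  tau <- rm * cm / 1000                    # ms
  (i_nA * 1e-9) * R * (1 - exp(-t_ms / tau)) * 1000
}

## Analytic somatic step response of the ball-and-stick (lumped soma +
## finite sealed cable), via the eigenfunction expansion of the cable
## equation: separation of variables with eigencondition
## tan(beta L) = -sigma beta (sigma = soma-to-cable conductance ratio),
## including the uniform beta = 0 membrane mode, with coefficients from
## the capacitance-weighted (point soma mass) inner product.  Fully
## independent of the compartmental time stepper.
rall_step_soma_mV <- function(t_ms, i_nA, soma_diam_um, stick_diam_um,
                              stick_len_um, cm, rm, ra, nterms = 120) {
  ds <- soma_diam_um * 1e-4; d <- stick_diam_um * 1e-4
  l <- stick_len_um * 1e-4; a <- d / 2
  As <- pi * ds^2
  Gs <- As / rm
  Cs <- cm * 1e-6 * As
  lambda <- sqrt(rm * a / (2 * ra))
  Ginf <- pi * a^2 / (ra * lambda)
  L <- l / lambda
  tau_m <- rm * cm * 1e-3
  sigma <- Gs / Ginf
  I <- i_nA * 1e-9
  V0 <- I / (Gs + Ginf * tanh(L))
  vss <- function(X) V0 * cosh(L - X) / cosh(L)
  betas <- c(0, vapply(seq_len(nterms), function(n) {
    lo <- (n - 0.5) * pi / L + 1e-9
    hi <- n * pi / L - 1e-9
    stats::uniroot(function(b) tan(b * L) + sigma * b, c(lo, hi),
                   tol = 1e-14)$root
  }, numeric(1)))
  cX <- cm * 1e-6 * pi * d * lambda       # F per unit electrotonic length
  eps <- Cs / cX
  Xs <- seq(0, L, length.out = 4001)
  h <- diff(Xs)[1]
  trap <- function(f) sum(f[-1] + f[-length(f)]) / 2 * h
  coefs <- vapply(betas, function(b) {
    phi <- cos(b * (L - Xs))
    num <- trap(vss(Xs) * phi) + eps * vss(0) * cos(b * L)
    den <- trap(phi^2) + eps * cos(b * L)^2
    num / den
  }, numeric(1))
  vapply(t_ms, function(t) {
    1000 * (vss(0) -
              sum(coefs * cos(betas * L) * exp(-t / tau_m * (1 + betas^2))))
  }, numeric(1))
}

## brief-pulse response by superposition of step on/off
rall_pulse_soma_mV <- function(t_ms, i_nA, dur_ms, ...) {
  v_on <- rall_step_soma_mV(t_ms, i_nA, ...)
  v_off <- rep(0, length(t_ms))
  late <- t_ms > dur_ms
  v_off[late] <- rall_step_soma_mV(t_ms[late] - dur_ms, i_nA, ...)
  v_on - v_off
}
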