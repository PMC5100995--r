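test_that("isopotential compartment reproduces the RC charging curve", {
  m <- make_soma_only()
  cable <- build_cable(discretize(m), passive_params(1, 20000, 150, 0))
  tr <- simulate(cable, current_step(0.05, 0, 50), dt = 0.025, t_stop = 50)
  van <- rc_step_mV(tr$time_ms, 0.05, 20, 1, 20000)
  ss <- van[length(van)]
  expect_lt(max(abs(tr$v_mV[, 1] - van)) / ss, 1e-3)   # within 0.1%
})

test_that("halving dt reduces the RC error fourfold (second order)", {
  m <- make_soma_only()
  cable <- build_cable(discretize(m), passive_params(1, 20000, 150, 0))
  errs <- vapply(c(0.2, 0.1, 0.05, 0.025), function(dt) {
    tr <- simulate(cable, current_step(0.05, 0, 40), dt = dt, t_stop = 40)
    max(abs(tr$v_mV[, 1] - rc_step_mV(tr$time_ms, 0.05, 20, 1, 20000)))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))
})

test_that("ball-and-stick transient matches the cable-equation expansion", {
  bs <- make_ball_stick(soma_diam = 20, stick_diam = 2, stick_len = 600)
  cable <- build_cable(discretize(bs, dx_rule(fixed_um = 5)),
                       passive_params(1, 20000, 150, 0))
  tr <- simulate(cable, current_step(0.2, 0, 2), dt = 0.01, t_stop = 60)
  van <- rall_pulse_soma_mV(tr$time_ms, 0.2, 2, soma_diam_um = 20,
                            stick_diam_um = 2, stick_len_um = 600,
                            cm = 1, rm = 20000, ra = 150)
  sel <- tr$time_ms > 2.5
  expect_lt(max(abs(tr$v_mV[sel, 1] - van[sel])) / max(abs(van)), 0.01)
})

test_that("zero stimulus stays at rest and balances charge to 1e-9", {
  bs <- make_ball_stick()
  cable <- build_cable(discretize(bs, dx_rule(fixed_um = 25)),
                       passive_params(0.5, 40000, 200, -70))
  tr <- simulate(cable, NULL, dt = 0.05, t_stop = 30, check_balance = TRUE)
  expect_lt(max(abs(tr$v_mV + 70)), 1e-9)
  expect_lt(tr$max_balance_resid, 1e-9)
  ## balance also holds mid-transient
  tr2 <- simulate(cable, current_step(0.2, 5, 2), dt = 0.05, t_stop = 30,
                  check_balance = TRUE)
  expect_lt(tr2$max_balance_resid, 1e-9)
})

test_that("spike detection interpolates upward crossings only", {
  t <- seq(0, 20, by = 0.1)
  flat <- list(time_ms = t, v_mV = rep(-65, length(t)))
  expect_length(detect_spikes(flat), 0)
  sine <- list(time_ms = t, v_mV = 30 * sin(2 * pi * t / 10) - 5)
  cross <- detect_spikes(sine)
  expect_length(cross, 2)           # two upward zero crossings in 20 ms
  ## linear interpolation puts the crossing where sin(2 pi t/10) = 1/6
  expect_equal(cross[1], 10 / (2 * pi) * asin(5 / 30), tolerance = 1e-2)
})

test_that("conduction velocity arithmetic and degenerate cases", {
  t <- seq(0, 5, by = 0.005)
  bump <- function(t0) 120 * exp(-((t - t0) / 0.15)^2) - 65
  a <- list(time_ms = t, v_mV = bump(1.0))
  b <- list(time_ms = t, v_mV = bump(1.5))
  expect_equal(conduction_velocity(a, b, 1000), 2.0, tolerance = 1e-2)
  expect_error(conduction_velocity(a, a, 1000), "delay")
  none <- list(time_ms = t, v_mV = rep(-65, length(t)))
  expect_error(conduction_velocity(a, none, 1000), "one spike")
})

test_that("active soma fires on a 300 pA pulse", {
  m <- make_soma_only()
  cable <- build_cable(discretize(m), passive_params(0.45, 38907, 203, -85),
                       hh = hh_channels())
  tr <- simulate(cable, current_step(0.3, 5, 10), dt = 0.025, t_stop = 30)
  expect_gte(length(detect_spikes(tr)), 1)
  ## with its dendritic load the cell rests stably without input
  bs <- make_ball_stick()
  cable2 <- build_cable(discretize(bs, dx_rule(fixed_um = 25)),
                        passive_params(0.45, 38907, 203, -85),
                        hh = hh_channels())
  tr0 <- simulate(cable2, NULL, dt = 0.025, t_stop = 300)
  expect_length(detect_spikes(tr0), 0)
})

test_that("passive voltages stay between rest and the synaptic reversal", {
  bs <- make_ball_stick()
  sp <- add_spine(bs, 2)
  cable <- build_cable(discretize(sp$morph, dx_rule(fixed_um = 25)),
                       passive_params(0.5, 40000, 200, -70))
  ev <- data.frame(onset_ms = 2)
  ev$location <- list(list(section = sp$head_id, pos = 0.5))
  ev$kinetics <- list(ampa_kinetics(5))   # strong synapse
  tr <- simulate(cable, synapse_protocol(ev), dt = 0.025, t_stop = 60,
                 record = list("soma", list(section = sp$head_id, pos = 0.5)))
  expect_true(all(tr$v_mV >= -70 - 1e-9))
  expect_true(all(tr$v_mV <= 0 + 1e-9))
})

test_that("grid refinement changes the somatic peak by less than 0.5%", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  peak <- function(frac) {
    comps <- apply_spine_correction(
      discretize(bs, dx_rule(lambda_frac = frac)), 1.9, 60)
    cable <- build_cable(comps, passive_params(0.5, 40000, 200, 0))
    max(simulate(cable, current_step(0.2, 10, 2), dt = 0.025,
                 t_stop = 40)$v_mV)
  }
  p1 <- peak(0.1); p2 <- peak(0.05)
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("non-uniform Rm and Ih enter the cable as configured", {
  bs <- make_ball_stick()
  comps <- discretize(bs, dx_rule(fixed_um = 50))
  nu <- nonuniform_rm(40000, 10000, 200)
  cab <- build_cable(comps, passive_params(0.5, 99999, 150, -70),
                     rm_nonuniform = nu)
  g_expect <- comps$area_um2 * 1e-2 / rm_profile(comps$path_um, nu)
  expect_equal(cab$g_pas_uS, g_expect, tolerance = 1e-12)

  cab2 <- build_cable(comps, passive_params(0.5, 40000, 150, -70),
                      ih = ih_distribution(0.2))
  ap <- comps$kind == "apical"
  expect_true(all(cab2$g_h_uS[ap] > 0))
  expect_equal(cab2$g_h_uS[comps$kind == "soma"],
               0.2 * comps$area_um2[comps$kind == "soma"] * 1e-5)
  ## Ih depolarizes the resting potential after settling
  tr <- simulate(cab2, NULL, dt = 0.05, t_stop = 10)
  expect_gt(tr$v_mV[1, 1], -70)
})
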