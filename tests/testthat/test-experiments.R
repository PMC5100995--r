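## Functional protocols run on the small synthetic ball-and-stick (speed);
## the human-scale random tree is exercised in the acceptance suite.

test_that("EPSP transfer: lower Cm gives larger, earlier somatic EPSPs", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  ep <- epsp_transfer(bs, cm_values = c(0.45, 0.9),
                      rule = dx_rule(fixed_um = 25))
  expect_equal(nrow(ep), 4)     # apical/basal x two Cm conditions
  expect_false(any(ep$spike))
  for (site in c("apical", "basal")) {
    lo <- ep[ep$site == site & ep$cm == 0.45, ]
    hi <- ep[ep$site == site & ep$cm == 0.9, ]
    expect_gt(lo$soma_peak_mV, hi$soma_peak_mV)
    expect_lt(lo$delay_ms, hi$delay_ms)
    ## passive attenuation: somatic peak strictly below the spine head
    expect_lt(lo$soma_peak_mV, lo$local_peak_mV)
    expect_lt(hi$soma_peak_mV, hi$local_peak_mV)
  }
})

test_that("synapse-count curve is a probability curve with sane endpoints", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  s <- synapses_to_spike(bs, cm = 0.45, N_grid = c(0, 2, 6, 12, 24, 48),
                         n_trials = 8, rule = dx_rule(fixed_um = 25),
                         seed = 5)
  expect_equal(s$curve$p_spike[1], 0)              # no synapses, no spike
  expect_equal(s$curve$p_spike[nrow(s$curve)], 1)  # saturation
  expect_true(all(s$curve$p_spike >= 0 & s$curve$p_spike <= 1))
  expect_false(is.na(s$n50))
  ## bit-for-bit reproducible under the seed
  s2 <- synapses_to_spike(bs, cm = 0.45, N_grid = c(0, 2, 6, 12, 24, 48),
                          n_trials = 8, rule = dx_rule(fixed_um = 25),
                          seed = 5)
  expect_identical(s$curve, s2$curve)
})

test_that("more synapses are needed to spike at the higher Cm", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  grid <- c(0, 2, 4, 8, 16, 32, 64)
  lo <- synapses_to_spike(bs, cm = 0.45, N_grid = grid, n_trials = 10,
                          rule = dx_rule(fixed_um = 25), seed = 7)
  hi <- synapses_to_spike(bs, cm = 0.9, N_grid = grid, n_trials = 10,
                          rule = dx_rule(fixed_um = 25), seed = 7)
  expect_lt(lo$n50, hi$n50)
})

test_that("conduction velocity decreases with Cm; axon Rm barely matters", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  av <- axon_velocity(bs, cm_values = c(0.45, 0.675, 0.9),
                      rule = dx_rule(fixed_um = 20))
  expect_true(all(diff(av$velocity_m_s) < 0))
  expect_gt(attr(av, "pct_increase"), 0)
  ## halving the cell membrane's Rm (axon keeps its stated passive
  ## properties) changes velocity by well under 1%
  base <- axon_velocity(bs, cm_values = 0.9, rule = dx_rule(fixed_um = 20))
  half <- axon_velocity(bs, cm_values = 0.9, rm = 38907 / 2,
                        axon_rm = 38907, rule = dx_rule(fixed_um = 20))
  expect_lt(abs(half$velocity_m_s / base$velocity_m_s - 1), 0.01)
})

test_that("velocity is insensitive to axon length beyond 3 mm", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  v3 <- axon_velocity(bs, cm_values = 0.45, axon_length_um = 3000,
                      rule = dx_rule(fixed_um = 20))$velocity_m_s
  v6 <- axon_velocity(bs, cm_values = 0.45, axon_length_um = 6000,
                      rule = dx_rule(fixed_um = 20))$velocity_m_s
  expect_lt(abs(v3 / v6 - 1), 0.02)
})

test_that("fixed-tau control pairs Cm and Rm to the same time constant", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  fx <- fixed_tau_control(bs, cm_pair = c(0.45, 0.9), rm_at_low = 38907,
                          rule = dx_rule(fixed_um = 25))
  expect_equal(fx$tau_m_ms[1], fx$tau_m_ms[2], tolerance = 1e-12)
  expect_equal(fx$tau_m_ms[1], 0.45 * 38907 / 1000, tolerance = 1e-12)
  ## compare against the fixed-Rm comparison on the same cell
  free <- epsp_transfer(bs, cm_values = c(0.45, 0.9),
                        rule = dx_rule(fixed_um = 25))
  for (site in c("apical", "basal")) {
    d_fixed_tau <- diff(fx$epsp$delay_ms[fx$epsp$site == site])
    d_fixed_rm <- diff(free$delay_ms[free$site == site])
    expect_lt(abs(d_fixed_tau), abs(d_fixed_rm))   # smaller delay difference
    ## halved Rm attenuates more: smaller somatic EPSP at the high-Cm leg
    ep_tau <- fx$epsp[fx$epsp$site == site & fx$epsp$cm == 0.9, ]
    ep_rm <- free[free$site == site & free$cm == 0.9, ]
    expect_lt(ep_tau$soma_peak_mV, ep_rm$soma_peak_mV)
  }
})
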