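test_that("averaging subtracts baseline and suppresses noise by 1/sqrt(n)", {
  t <- seq(0, 50, by = 0.1)
  signal <- ifelse(t > 10, 5 * exp(-(t - 10) / 15), 0)
  ## identical sweeps: average is the sweep re-based to zero
  ss <- sweep_set(t, matrix(signal - 70, length(t), 8), amp_pA = 200)
  avg <- average_transient(ss)
  expect_equal(avg$v_mV, signal, tolerance = 1e-12)
  expect_equal(avg$rest_mV, -70)
  ## junction correction shifts only the reported rest
  ssj <- sweep_set(t, matrix(signal - 70, length(t), 8), amp_pA = 200,
                   junction_mV = 16)
  expect_equal(average_transient(ssj)$rest_mV, -86)
  expect_equal(average_transient(ssj)$v_mV, avg$v_mV)

  withr::with_seed(42, {
    n <- 50; sd <- 0.2
    sweeps <- matrix(signal, length(t), n) +
      matrix(rnorm(length(t) * n, 0, sd), length(t))
    ssn <- sweep_set(t, sweeps, amp_pA = 200)
    res <- average_transient(ssn)$v_mV - signal
    expect_lt(sd(res), 1.4 * sd / sqrt(n))
    expect_gt(sd(res), 0.6 * sd / sqrt(n))
  })
  expect_error(sweep_set(t, matrix(numeric(0), length(t), 0), 200), "at least")
})

test_that("rmsd is a windowed metric", {
  t <- seq(0, 100, by = 0.5)
  a <- list(time_ms = t, v_mV = sin(t / 10))
  b <- list(time_ms = t, v_mV = sin(t / 10) + 1)
  cc <- list(time_ms = t, v_mV = cos(t / 7))
  w <- c(10, 90)
  expect_equal(rmsd(a, a, w), 0)
  expect_equal(rmsd(a, b, w), 1, tolerance = 1e-12)
  expect_equal(rmsd(a, b, w), rmsd(b, a, w))
  expect_lte(rmsd(a, cc, w), rmsd(a, b, w) + rmsd(b, cc, w))
  expect_error(rmsd(a, b, c(200, 300)), "empty")
  ## the window excludes the first ms after pulse offset
  avg <- list(time_ms = t, v_mV = sin(t / 10), delay_ms = 10, dur_ms = 2)
  w2 <- cablefit:::fit_window(avg, fit_config(window_ms = c(1, 100)))
  expect_equal(w2[1], 13)   # delay + duration + 1 ms
  expect_equal(w2[2], 100)  # clamped to the trace end
})

test_that("noiseless synthetic data returns the ground truth", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0,
                         truth = passive_params(0.5, 40000, 200))
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  fr <- fit_passive(m, sw, fit_config(n_starts = 2, seed = 7))
  expect_lt(abs(fr$params$cm / 0.5 - 1), 0.01)
  expect_lt(abs(fr$params$rm / 40000 - 1), 0.01)
  expect_lt(fr$rmsd_mV, 1e-4)
  expect_true(fr$converged)
  ## validation on the other five stimuli is as good as the fit
  expect_true(all(fr$validation$rmsd_mV < 1e-3))
})

test_that("fit is invariant to sweep order and deterministic in the seed", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0.2, seed = 3)
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  ss <- sw[[which(vapply(sw, function(s) s$amp_pA, 1) == 200)]]
  cfg <- fit_config(n_starts = 2, seed = 11)
  f1 <- fit_passive(m, ss, cfg)
  perm <- withr::with_seed(1, sample(ncol(ss$v_mV)))
  ss2 <- sweep_set(ss$time_ms, ss$v_mV[, perm], ss$amp_pA, ss$delay_ms,
                   ss$dur_ms)
  f2 <- fit_passive(m, ss2, cfg)
  f3 <- fit_passive(m, ss, cfg)
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
  expect_identical(f1$params, f3$params)
})

test_that("fit on the strong pulse validates across amplitudes (noisy)", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0.2, seed = 5)
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  fr <- fit_passive(m, sw, fit_config(n_starts = 2, seed = 2))
  expect_lt(abs(fr$params$cm / 0.5 - 1), 0.05)
  ## every other amplitude reproduced within 2x the fit RMSD
  fit_rmsd <- fr$validation$rmsd_mV[fr$validation$fitted]
  expect_true(all(fr$validation$rmsd_mV <= 2 * fit_rmsd + 1e-12))
})

test_that("constrained profile has its minimum at the truth for Cm", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0.2, seed = 9)
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  grid <- c(0.4, 0.5, 0.7, 1.0)
  prof <- profile_constrained(m, sw, "cm", grid,
                              config = fit_config(seed = 1),
                              warm_start = c(cm = 0.5, rm = 40000, ra = 200))
  expect_equal(grid[which.min(prof$rmsd_mV)], 0.5)
  expect_gt(prof$rmsd_mV[grid == 1.0], prof$rmsd_mV[grid == 0.5])
})

test_that("fixing Ih at zero reduces exactly to the passive fit", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0, seed = 2)
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  cfg <- fit_config(n_starts = 2, seed = 4)
  f0 <- fit_passive(m, sw, cfg)
  fih <- fit_with_ih(m, sw, g_soma = 0, config = cfg)
  expect_equal(fih$params, f0$params, tolerance = 1e-12)
  expect_equal(fih$g_soma, 0)
})

test_that("assuming Ih inflates the fitted Cm on passively generated data", {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0, seed = 2)
  m <- gen_morphology(spec)
  sw <- gen_transients(m, spec)
  cfg <- fit_config(n_starts = 2, seed = 4)
  f0 <- fit_passive(m, sw, cfg)
  f2 <- fit_with_ih(m, sw, g_soma = 0.2, config = cfg)
  expect_gt(f2$params$cm, f0$params$cm)
  expect_gt(f2$rmsd_mV, f0$rmsd_mV)   # fit quality degrades
  ## constraining Cm at the truth with Ih: the early window (capacitive
  ## regime) is matched much better than the full window
  fc <- fit_with_ih(m, sw, g_soma = 0.2, config = cfg,
                    fixed = list(cm = 0.5))
  expect_lt(fc$early_rmsd_mV, fc$rmsd_mV)
})
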