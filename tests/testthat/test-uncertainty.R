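make_noisy_set <- function(seed = 1, n_sweeps = 50, noise = 0.2) {
  spec <- synthetic_spec("ball_and_stick", noise_sd_mV = noise,
                         n_sweeps = n_sweeps, seed = seed,
                         stim_amps_pA = 200)
  m <- gen_morphology(spec)
  list(morph = m, ss = gen_transients(m, spec)[[1]])
}

test_that("balanced resampling uses every sweep exactly n_replicates times", {
  d <- make_noisy_set()
  plan <- bootstrap_plan(n_sweeps = 50, n_replicates = 40, seed = 6)
  reps <- balanced_resample(d$ss, plan)
  idx <- attr(reps, "index_matrix")
  expect_equal(dim(idx), c(40, 50))
  expect_true(all(table(idx) == 40))
  ## grand mean of replicate averages equals the overall mean exactly
  gm <- Reduce(`+`, lapply(reps, function(r) r$v_mV)) / length(reps)
  expect_equal(gm, average_transient(d$ss)$v_mV, tolerance = 1e-12)
  ## identical sweeps give identical replicates
  same <- sweep_set(d$ss$time_ms, matrix(d$ss$v_mV[, 1], nrow(d$ss$v_mV), 50),
                    200)
  reps2 <- balanced_resample(same, plan)
  expect_equal(reps2[[1]]$v_mV, reps2[[25]]$v_mV, tolerance = 1e-12)
  ## reproducible bit-for-bit under the seed
  reps3 <- balanced_resample(d$ss, plan)
  expect_identical(attr(reps3, "index_matrix"), idx)
})

test_that("statistical errors vanish for noiseless sweeps", {
  d <- make_noisy_set(noise = 0)
  cfg <- fit_config(n_starts = 2, seed = 3)
  fit <- fit_passive(d$morph, d$ss, cfg)
  se <- statistical_errors(d$morph, d$ss, bootstrap_plan(50, 5, seed = 2),
                           cfg, fit = fit)
  expect_true(all(se$sd < c(cm = 1e-4, rm = 10, ra = 1)))
  expect_length(se$failed, 0)
})

test_that("bootstrap parameter spread tracks an independent Monte Carlo", {
  ## same cell, 12 bootstrap replicates vs 12 fresh noise realisations
  cfg <- fit_config(n_starts = 1, seed = 3)
  d <- make_noisy_set(seed = 21)
  fit <- fit_passive(d$morph, d$ss, cfg,
                     start = c(cm = 0.5, rm = 40000, ra = 200))
  se <- statistical_errors(d$morph, d$ss, bootstrap_plan(50, 12, seed = 5),
                           cfg, fit = fit)
  mc <- vapply(1:12, function(i) {
    spec <- synthetic_spec("ball_and_stick", noise_sd_mV = 0.2, seed = 100 + i,
                           stim_amps_pA = 200)
    sw <- gen_transients(d$morph, spec)[[1]]
    fr <- fit_passive(d$morph, sw, cfg, start = c(cm = 0.5, rm = 40000,
                                                  ra = 200))
    fr$params$cm
  }, numeric(1))
  expect_lt(se$sd[["cm"]], 3 * sd(mc))
  expect_gt(se$sd[["cm"]], sd(mc) / 3)
})

test_that("morphology perturbations behave as stated", {
  bs <- make_ball_stick()
  p <- perturb_morphology(bs, length_scale = 1.1)
  ## lengths scale; diameters do not, so lateral area scales linearly
  expect_equal(total_area(p, kinds = "apical"),
               1.1 * total_area(bs, kinds = "apical"), tolerance = 1e-9)
  expect_equal(max_path_distance(p), 1.1 * max_path_distance(bs),
               tolerance = 5e-3)
  p2 <- perturb_morphology(bs, diam_add_um = 0.3, diam_scale = 1.1)
  d0 <- bs$sections[["2"]]$points[1, "diam"]
  expect_equal(p2$sections[["2"]]$points[1, "diam"], (d0 + 0.3) * 1.1)
  ## clipping floor
  thin <- perturb_morphology(bs, diam_add_um = -5)
  expect_true(all(vapply(thin$sections, function(s)
    all(s$points[, "diam"] >= 0.1), logical(1))))
  expect_gt(attr(thin, "n_clipped"), 0)
})

test_that("systematic spread is zero for zero SDs and Cm drops when diameters double", {
  d <- make_noisy_set(noise = 0)
  cfg <- fit_config(n_starts = 1, seed = 3)
  fit <- fit_passive(d$morph, d$ss, cfg,
                     start = c(cm = 0.5, rm = 40000, ra = 200))
  spec0 <- systematic_error_spec(0, 0, 0, 0, 0, n_samples = 3, seed = 1)
  sy <- systematic_errors(d$morph, d$ss, spec0, cfg, fit = fit)
  expect_true(all(sy$sd < c(1e-4, 10, 1)))

  ## doubled diameters -> more membrane -> less specific capacitance needed
  big <- perturb_morphology(d$morph, diam_scale = 2)
  avg <- average_transient(d$ss)
  ss1 <- sweep_set(avg$time_ms, matrix(avg$v_mV, ncol = 1), 200, 10, 2)
  fr_big <- fit_passive(big, ss1, cfg, start = c(cm = 0.5, rm = 40000,
                                                 ra = 200))
  expect_lt(fr_big$params$cm, fit$params$cm)
})
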