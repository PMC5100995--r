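test_that("SWC loading builds the tree and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# minimal tree",
               "1 1 0 0 0 10 -1",
               "2 3 0 0 0 1 1",
               "3 3 0 0 50 1 2"), f)
  m <- load_swc(f)
  expect_s3_class(m, "cable_morphology")
  expect_length(m$sections, 2)
  kinds <- vapply(m$sections, function(s) s$kind, character(1))
  expect_setequal(unname(kinds), c("soma", "basal"))
  expect_equal(sum(vapply(m$sections, function(s) is.na(s$parent), logical(1))), 1)

  f2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "5 3 0 0 50 1 99"), f2)
  expect_error(load_swc(f2), "missing parent")

  f3 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 0 -1"), f3)
  expect_error(load_swc(f3), "non-positive radius")
})

test_that("surface areas follow frustum/sphere geometry", {
  cyl <- section(1, "basal", rbind(c(0, 0, 0, 2), c(0, 0, 100, 2)))
  expect_equal(surface_area(cyl), pi * 2 * 100, tolerance = 1e-10)

  fr <- section(1, "basal", rbind(c(0, 0, 0, 1), c(0, 0, 10, 2)))
  expect_equal(surface_area(fr), pi * 1.5 * sqrt(100 + 0.25), tolerance = 1e-10)
  expect_equal(surface_area(fr), 47.18, tolerance = 1e-3)

  soma <- section(1, "soma", matrix(c(0, 0, 0, 10), 1))
  expect_equal(surface_area(soma), pi * 100, tolerance = 1e-10)

  ## synthetic ball-and-stick: one 400 um, 2 um apical cylinder
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  expect_equal(total_area(bs, kinds = "apical"), pi * 2 * 400,
               tolerance = 1e-6)
})

test_that("discretization gives odd centred grids and exact partitions", {
  bs <- make_ball_stick(stick_len = 400)
  comps <- discretize(bs, dx_rule(fixed_um = 40))
  stick <- comps[comps$kind == "apical", ]
  expect_equal(nrow(stick), 11)           # ceil(400/40) = 10, forced odd
  expect_equal(sum(stick$length_um), 400, tolerance = 1e-9)
  expect_equal(sum(stick$area_um2), pi * 2 * 400, tolerance = 1e-6)

  soma_only <- make_soma_only()
  expect_equal(nrow(discretize(soma_only)), 1)

  degen <- morphology(list(
    section(1, "soma", matrix(c(0, 0, 0, 10), 1)),
    section(2, "basal", rbind(c(0, 0, 0, 1), c(0, 0, 0, 1)), parent = 1)))
  expect_error(discretize(degen), "zero-length")
})

test_that("path distance is additive along the tree and zero at the soma", {
  spec <- synthetic_spec("random_tree", target_path_um = 900, seed = 3)
  m <- gen_morphology(spec)
  comps <- discretize(m, dx_rule(fixed_um = 20))
  expect_equal(comps$path_um[comps$kind == "soma"], 0)
  ## child path = parent path + half-lengths of the two compartments
  for (i in which(comps$parent > 0)) {
    p <- comps$parent[i]
    step <- (comps$length_um[i] + comps$length_um[p]) / 2
    if (comps$section_id[i] == comps$section_id[p]) {
      expect_equal(comps$path_um[i] - comps$path_um[p], step,
                   tolerance = 1e-9)
    } else {
      expect_gte(comps$path_um[i] + 1e-9, comps$path_um[p])
    }
  }
})

test_that("spine correction marks only distal dendrites and bounds area", {
  bs <- gen_morphology(synthetic_spec("ball_and_stick"))
  comps <- discretize(bs, dx_rule(fixed_um = 20))
  cor <- apply_spine_correction(comps, F = 1.9, start_distance_um = 60)
  expect_true(all(cor$spine_factor[cor$path_um < 60] == 1))
  expect_true(all(cor$spine_factor[cor$kind == "apical" & cor$path_um >= 60] == 1.9))
  expect_true(all(cor$spine_factor[cor$kind == "soma"] == 1))

  ## effective area strictly between raw and raw * F
  eff <- sum(cor$area_um2 * cor$spine_factor)
  raw <- sum(cor$area_um2)
  expect_gt(eff, raw)
  expect_lt(eff, raw * 1.9)

  ## identity and error cases
  id <- apply_spine_correction(comps, F = 1, start_distance_um = 0)
  expect_true(all(id$spine_factor == 1))
  expect_error(apply_spine_correction(comps, F = 0.5), "F")

  ## mouse mode: whole-tree correction
  mouse <- apply_spine_correction(comps, F = 1.9, start_distance_um = 0)
  expect_true(all(mouse$spine_factor[mouse$kind %in% c("basal", "apical")] == 1.9))
})

test_that("write/load round trip preserves geometry", {
  spec <- synthetic_spec("random_tree", target_path_um = 1000, seed = 5)
  m <- gen_morphology(spec)
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f1)
  m2 <- load_swc(f1)
  write_swc(m2, f2)
  expect_identical(readLines(f1)[-1], readLines(f2)[-1])
  expect_equal(total_area(m2), total_area(m), tolerance = 1e-4)
  expect_equal(max_path_distance(m2), max_path_distance(m), tolerance = 5e-3)
})

test_that("morphology construction enforces tree invariants", {
  s1 <- section(1, "soma", matrix(c(0, 0, 0, 10), 1))
  s2 <- section(2, "basal", rbind(c(0, 0, 0, 1), c(0, 0, 10, 1)), parent = 7)
  expect_error(morphology(list(s1, s2)), "missing parent")
  expect_error(morphology(list(s1, s1)), "duplicate")
  expect_error(section(1, "soma", matrix(c(0, 0, 0, -1), 1)), "diameter")
})

test_that("explicit spines attach with the stated geometry", {
  bs <- make_ball_stick()
  sp <- add_spine(bs, at_section = 2)
  expect_length(sp$morph$sections, 4)
  head_sec <- sp$morph$sections[[as.character(sp$head_id)]]
  expect_equal(surface_area(head_sec), 2.8, tolerance = 1e-9)
  neck_sec <- sp$morph$sections[[as.character(sp$neck_id)]]
  expect_equal(section_length <- sqrt(sum((neck_sec$points[2, 1:3] -
                                             neck_sec$points[1, 1:3])^2)),
               1.35, tolerance = 1e-9)

  ## fast path produces the same electrical elements
  comps <- discretize(bs, dx_rule(fixed_um = 20))
  at <- which(comps$kind == "apical")[5]
  ext <- attach_spines(comps, at)
  expect_equal(nrow(ext$comps), nrow(comps) + 2)
  neck <- ext$comps[nrow(comps) + 1, ]
  expect_equal(neck$area_um2, pi * 0.25 * 1.35, tolerance = 1e-9)
  expect_equal(ext$comps$area_um2[ext$head_comps], 2.8)
  ## neck axial resistance at Ra = 203 lands in the stated 50-80 MOhm
  total_neck_unit <- neck$ra_unit_Mohm - comps$dist_half_unit_Mohm[at] +
    ext$comps$ra_unit_Mohm[ext$head_comps]
  expect_equal(203 * total_neck_unit, spine_neck_resistance(203),
               tolerance = 1e-9)
})
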