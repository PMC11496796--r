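test_that("slice-summation volume matches the analytic ball and exact counting", {
  ball <- digital_ball(r = 30, spacing = 1)
  v <- la_volume_slice_sum(ball, c(1, 1, 1))
  expect_equal(v, 4 / 3 * pi * 30^3 / 1000, tolerance = 0.01)
  expect_identical(v, sum(ball) * 1 / 1000)

  empty <- array(FALSE, c(4, 4, 2))
  expect_warning(v0 <- la_volume_slice_sum(empty, c(1, 1, 1)), "empty")
  expect_identical(v0, 0)

  one <- array(FALSE, c(4, 4, 2)); one[2, 2, 1] <- TRUE
  expect_equal(la_volume_slice_sum(one, c(1.25, 1.25, 2.5)), 0.00390625)
})

test_that("EAT volume is voxel count times voxel volume", {
  expect_identical(eat_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
  expect_identical(eat_volume(m, c(1, 1, 1)), 1)
  ph <- generate_la_phantom(tiny_config(seed = 2))
  expect_identical(eat_volume(ph$masks$eat, ph$config$spacing),
                   sum(ph$masks$eat) * prod(ph$config$spacing) / 1000)
})

test_that("relative and absolute areas are consistent by construction", {
  flags <- c(rep(TRUE, 25), rep(FALSE, 75))
  expect_identical(relative_area(flags), 25)
  expect_identical(relative_area(rep(TRUE, 10)), 100)
  expect_identical(relative_area(rep(FALSE, 10)), 0)
  expect_error(relative_area(logical(0)), "empty")
  expect_equal(absolute_area(flags, 113), 28.25)
  expect_identical(absolute_area(flags, 113) / 113, relative_area(flags) / 100)
})

test_that("mesh area scales quadratically with linear dimension", {
  sh1 <- shell_mask(6, 9, 26, 1)
  sh2 <- shell_mask(12, 18, 50, 1)
  a1 <- wall_surface_area(build_wall_mesh(sh1$wall, sh1$spacing))
  a2 <- wall_surface_area(build_wall_mesh(sh2$wall, sh2$spacing))
  expect_equal(a2 / a1, 4, tolerance = 0.05)
  empty_mesh <- list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3))
  expect_error(wall_surface_area(empty_mesh), "faces")
})

test_that("BSA follows Mosteller with hand-checked values", {
  expect_equal(bsa(180, 80), 2)
  expect_equal(bsa(36, 100), 1)
  expect_error(bsa(0, 70), "positive")
  expect_equal(bsa(180, 80, formula = "dubois"),
               0.007184 * 180^0.725 * 80^0.425)
})

test_that("subject record assembles metrics, indices and flags", {
  flags_f <- c(rep(TRUE, 20), rep(FALSE, 80))
  flags_a <- rep(c(TRUE, FALSE), 50)
  rec <- build_subject_record("S1", "paroxysmal",
                              la_volume_ml = 180, eat_volume_ml = 12,
                              wall_area_cm2 = 113,
                              eat_adjacent_flags = flags_a,
                              fibrosis_flags = list(mvsi = flags_f),
                              covariates = list(height_cm = 180, weight_kg = 80,
                                                lvef_pct = 55))
  expect_equal(rec$bsa_m2, 2)
  expect_equal(rec$la_volume_index, 90)
  expect_equal(rec$fibrosis_pct_mvsi, 20)
  expect_equal(rec$overlap_pct_mvsi,
               100 * mean(flags_f & flags_a))
  expect_lte(rec$overlap_pct_mvsi, rec$fibrosis_pct_mvsi)
  expect_lte(rec$overlap_pct_mvsi, rec$eat_area_pct)

  # no overlap at all
  rec0 <- build_subject_record("S2", "persistent", 100, 5, 100,
                               eat_adjacent_flags = rep(FALSE, 100),
                               fibrosis_flags = list(mvsi = flags_f))
  expect_identical(rec0$overlap_pct_mvsi, 0)
  expect_identical(rec0$overlap_area_cm2_mvsi, 0)
  # missing covariates leave indexed fields NA and flag the record
  expect_true(is.na(rec0$la_volume_index))
  expect_true(isTRUE(attr(rec0, "missing_covariates")))
})

test_that("end-to-end metrics match phantom ground truth within tolerance", {
  ph <- generate_la_phantom(tiny_config(
    seed = 6, fibrosis_fraction = 0.2,
    si_levels = c(blood = 100, wall = 60, fibrosis = 150, mv = 80,
                  eat = 40, background = 30, sd = 0)))
  r <- run_case(ph, covariates = list(height_cm = 180, weight_kg = 80,
                                      lvef_pct = 60))
  expect_identical(r$record$fibrosis_pct_mvsi,
                   100 * length(ph$truth$fibrosis_lin) / sum(ph$masks$wall))
  expect_equal(r$record$fibrosis_pct_mvsi, 20, tolerance = 1e-3)
  expect_equal(r$record$eat_area_pct / 100,
               ph$truth$realized$eat_adjacent_fraction, tolerance = 0.25)
  expect_identical(r$record$la_volume_ml,
                   sum(ph$masks$la_cavity) * prod(ph$config$spacing) / 1000)
})
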