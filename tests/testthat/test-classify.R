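make_wall_case <- function() {
  ph <- generate_la_phantom(tiny_config(seed = 4))
  mesh <- orient_normals_outward(
    build_wall_mesh(ph$masks$wall, ph$config$spacing), ph$masks$blood_pool)
  list(ph = ph, wm = assign_voxel_normals(ph$masks$wall, mesh))
}

test_that("MV threshold is c * mean + k * SD of the ROI", {
  arr <- array(0, c(4, 4, 2))
  roi <- array(FALSE, c(4, 4, 2))
  roi[1:3, 1, 1] <- TRUE
  arr[roi] <- c(100, 110, 120)
  iv <- image_volume(arr)
  expect_equal(mv_threshold(iv, roi), 110)
  expect_equal(mv_threshold(iv, roi, c_mult = 1, k_sd = 1), 110 + 10)
  arr[roi] <- 200
  expect_equal(mv_threshold(image_volume(arr), roi, c_mult = 0.5), 100)
  expect_error(mv_threshold(iv, array(FALSE, c(4, 4, 2))), "empty")
})

test_that("SI classification recovers the designed fraction exactly without noise", {
  ph <- generate_la_phantom(tiny_config(
    seed = 2, fibrosis_fraction = 0.2,
    si_levels = c(blood = 100, wall = 60, fibrosis = 150, mv = 80,
                  eat = 40, background = 30, sd = 0)))
  mesh <- orient_normals_outward(
    build_wall_mesh(ph$masks$wall, ph$config$spacing), ph$masks$blood_pool)
  wm <- assign_voxel_normals(ph$masks$wall, mesh)
  water <- ph$volumes$water
  # the quota is exact in voxels; any threshold strictly between the tissue
  # means recovers it voxel-for-voxel
  quota_pct <- 100 * length(ph$truth$fibrosis_lin) / nrow(wm)
  for (thr in c(61, 80, 105, 149)) {
    rec <- relative_area(classify_fibrosis_si(water, wm, thr))
    expect_identical(rec, quota_pct)
    expect_equal(rec, 20, tolerance = 1e-3)
  }
  expect_equal(relative_area(classify_fibrosis_si(water, wm, 151)), 0)
  expect_equal(relative_area(classify_fibrosis_si(water, wm, 59)), 100)
})

test_that("IIR is wall SI over blood-pool mean", {
  cs <- make_wall_case()
  water <- cs$ph$volumes$water
  water$data[] <- 0
  water$data[cs$ph$masks$blood_pool] <- 200
  d <- dim(water$data)
  lin <- 1 + cs$wm$i + d[1] * (cs$wm$j + d[2] * cs$wm$k)
  water$data[lin] <- 264
  iir <- compute_iir(water, cs$wm, cs$ph$masks$blood_pool)
  expect_equal(unique(round(iir, 10)), 1.32)
  water$data[lin] <- 240
  expect_equal(unique(round(compute_iir(water, cs$wm, cs$ph$masks$blood_pool), 10)), 1.2)
  water$data[cs$ph$masks$blood_pool] <- 0
  expect_error(compute_iir(water, cs$wm, cs$ph$masks$blood_pool), "positive")
})

test_that("IIR thresholding is monotone: the 1.32 set is inside the 1.2 set", {
  for (s in 1:3) {
    ph <- generate_la_phantom(tiny_config(seed = s))
    r <- run_case(ph)
    expect_true(all(r$flags$fib_iir132 <= r$flags$fib_iir12))
  }
  expect_equal(sum(classify_fibrosis_iir(rep(1, 50), 1.2)), 0)
  expect_equal(sum(classify_fibrosis_iir(rep(2, 50), 1.32)), 50)
})

test_that("adjacency flags obey the ray rule on degenerate EAT masks", {
  cs <- make_wall_case()
  none <- classify_eat_adjacent(cs$wm, array(FALSE, dim(cs$ph$masks$eat)))
  expect_false(any(none))
  # EAT shell fully surrounding a thin wall at 1 mm gap: every ray reaches
  # it within 6 mm, so every wall voxel flags
  ph <- generate_la_phantom(tiny_config(seed = 5, eat_coverage = 1,
                                        n_eat_deposits = 1,
                                        wall_thickness_mm = 3, eat_gap_mm = 1))
  r <- run_case(ph)
  expect_true(all(r$flags$eat_adj))
})

test_that("polar-cap adjacency matches the solid-angle fraction", {
  ph <- generate_la_phantom(sphere_cap_config(seed = 2))
  r <- run_case(ph)
  expect_equal(mean(r$flags$eat_adj), 0.25, tolerance = 0.03 / 0.25)
})

test_that("adjacent fraction is invariant to a 90-degree in-plane rotation", {
  ph <- generate_la_phantom(tiny_config(seed = 8))
  base <- mean(run_case(ph)$flags$eat_adj)
  rot <- function(m) {
    d <- dim(m)
    aperm(m, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  volumes <- list(water = image_volume(rot(ph$volumes$water$data),
                                       ph$config$spacing))
  masks <- label_masks(rot(ph$masks$wall), rot(ph$masks$blood_pool),
                       rot(ph$masks$eat), mv_roi = rot(ph$masks$mv_roi))
  rotated <- mean(run_case(validate_case(volumes, masks))$flags$eat_adj)
  expect_equal(rotated, base, tolerance = 0.01 / base)
})

test_that("overlap is the voxelwise conjunction with subset structure", {
  f <- c(TRUE, TRUE, FALSE, FALSE)
  a <- c(TRUE, FALSE, TRUE, FALSE)
  expect_identical(classify_overlap(f, a), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_overlap(f, a[1:3]), "same wall voxels")
  cs <- make_wall_case()
  r <- run_case(cs$ph)
  for (m in c("mvsi", "iir12", "iir132")) {
    ov <- r$flags[[paste0("overlap_", m)]]
    expect_true(all(ov <= r$flags[[paste0("fib_", m)]]))
    expect_true(all(ov <= r$flags$eat_adj))
  }
})

test_that("independent fibrosis and EAT give near-product overlap over seeds", {
  p_times_q <- numeric(0); observed <- numeric(0)
  for (s in 1:5) {
    ph <- generate_la_phantom(tiny_config(seed = s, colocalization = 0,
                                          fibrosis_fraction = 0.15,
                                          eat_coverage = 0.25))
    r <- run_case(ph, methods = "iir12")
    p_times_q <- c(p_times_q, mean(r$flags$fib_iir12) * mean(r$flags$eat_adj))
    observed <- c(observed, mean(r$flags$overlap_iir12))
  }
  expect_lt(abs(mean(observed) - mean(p_times_q)), 0.05)
})
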