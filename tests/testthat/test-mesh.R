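test_that("sphere-shell mesh is closed with area near the analytic value", {
  sh <- shell_mask(r_in = 27, r_out = 30, n = 68, spacing = 1)
  mesh <- build_wall_mesh(sh$wall, sh$spacing)
  expect_true(mesh$closed)
  # outer sheet ~ 4*pi*30^2, inner ~ 4*pi*27^2; single-sided area is the mean
  ref <- 4 * pi * (27^2 + 30^2) / 2 / 100
  expect_equal(wall_surface_area(mesh), ref, tolerance = 0.03)
  expect_equal(sqrt(rowSums(mesh$vertex_normals^2)),
               rep(1, nrow(mesh$vertices)), tolerance = 1e-6)
})

test_that("single-voxel wall gives a small closed polyhedron; empty mask errors", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  mesh <- build_wall_mesh(m, c(1, 1, 1), smooth_sigma_mm = 0)
  expect_true(mesh$closed)
  expect_gt(nrow(mesh$faces), 4)
  expect_error(build_wall_mesh(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
})

test_that("area estimate is stable under grid refinement", {
  a1 <- wall_surface_area(build_wall_mesh(shell_mask(27, 30, 68, 1)$wall, c(1, 1, 1)))
  sh2 <- shell_mask(27, 30, 136, 0.5)
  a2 <- wall_surface_area(build_wall_mesh(sh2$wall, sh2$spacing))
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("outward orientation makes shell normals radial and is involutive", {
  sh <- shell_mask(r_in = 12, r_out = 15, n = 38, spacing = 1)
  mesh <- build_wall_mesh(sh$wall, sh$spacing)
  mesh <- orient_normals_outward(mesh, sh$blood)
  ctr <- (38 - 1) / 2
  rad <- sweep(mesh$vertices, 2, rep(ctr, 3))
  rad <- rad / sqrt(rowSums(rad^2))
  cosang <- rowSums(rad * mesh$vertex_normals)
  expect_gt(mean(cosang > cos(15 * pi / 180)), 0.99)

  # idempotence: orienting again changes nothing
  again <- orient_normals_outward(mesh, sh$blood)
  expect_identical(again$vertex_normals, mesh$vertex_normals)
  # involution: pre-flipping all normals inward gets fully flipped back
  flipped <- mesh
  flipped$vertex_normals <- -flipped$vertex_normals
  back <- orient_normals_outward(flipped, sh$blood)
  expect_equal(back$vertex_normals, mesh$vertex_normals)
})

test_that("voxel normals point away from the shell centroid on a convex phantom", {
  ph <- generate_la_phantom(tiny_config())
  mesh <- orient_normals_outward(
    build_wall_mesh(ph$masks$wall, ph$config$spacing), ph$masks$blood_pool)
  wm <- assign_voxel_normals(ph$masks$wall, mesh)
  ctr <- ph$truth$center_mm
  dt <- (wm$x - ctr[1]) * wm$nx + (wm$y - ctr[2]) * wm$ny + (wm$z - ctr[3]) * wm$nz
  expect_true(all(dt > 0))
})

test_that("nearest-vertex assignment matches a brute-force scan with id tie-break", {
  sh <- shell_mask(r_in = 6, r_out = 9, n = 24, spacing = 1)
  mesh <- build_wall_mesh(sh$wall, sh$spacing)
  wm <- assign_voxel_normals(sh$wall, mesh)
  expect_equal(nrow(wm), sum(sh$wall))  # one entry per wall voxel
  expect_lte(nrow(wm), 5000)
  pts <- as.matrix(wm[, c("x", "y", "z")])
  for (q in seq_len(nrow(pts))) {
    d2 <- colSums((t(mesh$vertices) - pts[q, ])^2)
    best <- min(d2)
    ids <- which(d2 <= best + 1e-9)
    expect_identical(wm$vertex_id[q], min(ids))
  }
})

test_that("a wall voxel coincident with a vertex inherits that vertex's normal", {
  m <- array(FALSE, c(7, 7, 7)); m[2:6, 2:6, 2:6] <- TRUE
  mesh <- build_wall_mesh(m, c(1, 1, 1), smooth_sigma_mm = 0)
  # midpoint-interpolated binary surface has vertices on half-integer grid
  # lines; query the exact vertex positions through the assignment path
  wm <- assign_voxel_normals(m, mesh)
  vid <- nearest_vertex_ids(mesh$vertices, mesh$vertices[1:10, , drop = FALSE], 1)
  expect_identical(vid, 1:10)
})

test_that("PLY export writes a parseable ASCII mesh", {
  sh <- shell_mask(6, 9, 24, 1)
  mesh <- build_wall_mesh(sh$wall, sh$spacing)
  f <- tempfile(fileext = ".ply")
  write_ply(mesh, f)
  lines <- readLines(f)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  expect_identical(nv, nrow(mesh$vertices))
  expect_identical(length(lines),
                   which(lines == "end_header") + nrow(mesh$vertices) + nrow(mesh$faces))
})
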