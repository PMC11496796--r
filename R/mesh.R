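#' Triangulated LA wall surface from the wall mask
#'
#' Extracts the isosurface of the binary intramural wall mask at level 0.5
#' in world millimetres. The raw binary isosurface of a voxel mask carries a
#' staircase bias that overestimates curved-surface area by ~9%, so the mask
#' is lightly Gaussian-smoothed (in mm, converted per axis to voxels) before
#' extraction; `smooth_sigma_mm = 0` disables this and extracts the blocky
#' midpoint surface. For a watertight shell the result is a closed,
#' consistently wound two-sheet mesh (endocardial + epicardial).
#'
#' @param wall logical 3D array (the intramural wall mask).
#' @param spacing,origin grid geometry (mm).
#' @param smooth_sigma_mm Gaussian pre-smoothing width in mm (default 1.25).
#' @return An object of class `wall_mesh`: `vertices` (n x 3 mm), `faces`
#'   (m x 3, 1-based), `vertex_normals` (unit, unoriented until
#'   [orient_normals_outward()]), `closed` flag, `spacing`, `origin`.
#' @export
build_wall_mesh <- function(wall, spacing, origin = c(0, 0, 0),
                            smooth_sigma_mm = 1.25) {
  if (inherits(wall, "image_volume")) {
    spacing <- wall$spacing; origin <- wall$origin; wall <- wall$data
  }
  storage.mode(wall) <- "logical"
  if (!any(wall)) stop("wall mask is empty; cannot build a surface", call. = FALSE)
  d <- dim(wall)
  # pad with background so masks touching the border still close
  field <- array(0, d + 2L)
  field[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.numeric(wall)
  if (smooth_sigma_mm > 0)
    field <- gaussian_smooth3d(field, smooth_sigma_mm / spacing)
  surf <- mt_isosurface(field, spacing, origin - spacing, 0.5)
  if (nrow(surf$faces) == 0L)
    stop("isosurface is empty (mask thinner than the smoothing width?)", call. = FALSE)
  closed <- mesh_is_closed(surf$faces)
  if (!closed)
    warning("wall surface is not closed; proceeding with best-effort mesh")
  vn <- vertex_normals(surf$vertices, surf$faces)
  structure(list(vertices = surf$vertices, faces = surf$faces,
                 vertex_normals = vn, closed = closed,
                 spacing = spacing, origin = origin),
            class = "wall_mesh")
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat("<wall_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, closed: ", x$closed,
      ", area (single-sided): ", format(wall_surface_area(x), digits = 4),
      " cm^2\n", sep = "")
  invisible(x)
}

mesh_is_closed <- function(faces) {
  nv <- max(faces)
  a <- c(faces[, 1], faces[, 2], faces[, 3])
  b <- c(faces[, 2], faces[, 3], faces[, 1])
  key <- pmin(a, b) * (nv + 1) + pmax(a, b)  # < 2^53 for any mesh here
  r <- rle(sort(key))
  all(r$lengths == 2L)
}

# Area-weighted vertex normals: sum of (unnormalised) face cross products,
# then normalised. Rotation-equivariant and smooth.
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], faces[, c])
      ids <- as.integer(rownames(acc))
      n[ids, ax] <- n[ids, ax] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Orient vertex normals away from the blood pool
#'
#' The raw two-sheet wall mesh has face-consistent normals that point away
#' from the wall tissue on both sheets — on the endocardial sheet that is
#' towards the blood pool, i.e. inward with respect to the LA. This step
#' flips every vertex normal whose direction does not increase the Euclidean
#' distance-from-blood-pool field, so all normals point "out from the LA".
#' Vertices with a degenerate (zero) field gradient fall back to the
#' direction from the blood-pool centroid.
#'
#' @param mesh a [build_wall_mesh()] result.
#' @param blood_pool logical 3D array on the same grid.
#' @return The mesh with outward `vertex_normals`.
#' @export
orient_normals_outward <- function(mesh, blood_pool) {
  if (inherits(blood_pool, "image_volume")) blood_pool <- blood_pool$data
  storage.mode(blood_pool) <- "logical"
  if (!any(blood_pool)) stop("blood pool mask is empty", call. = FALSE)
  D <- edt3d(blood_pool, mesh$spacing)
  g <- field_gradient_at(D, mesh$vertices, mesh$spacing, mesh$origin)
  glen <- sqrt(rowSums(g^2))
  degen <- glen < 1e-6
  if (any(degen)) {
    ctr <- colMeans(voxel_center(list(spacing = mesh$spacing, origin = mesh$origin),
                                 which_ijk(blood_pool)))
    g[degen, ] <- mesh$vertices[degen, , drop = FALSE] -
      matrix(ctr, sum(degen), 3, byrow = TRUE)
  }
  flip <- rowSums(mesh$vertex_normals * g) < 0
  mesh$vertex_normals[flip, ] <- -mesh$vertex_normals[flip, , drop = FALSE]
  mesh
}

# central-difference gradient of a scalar grid field, trilinearly sampled at
# arbitrary world points
field_gradient_at <- function(D, pts, spacing, origin) {
  h <- 0.5 * min(spacing)
  g <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- h
    up <- trilinear_sample(D, sweep(pts, 2, e, `+`), spacing, origin)
    dn <- trilinear_sample(D, sweep(pts, 2, e, `-`), spacing, origin)
    g[, ax] <- (up - dn) / (2 * h)
  }
  g
}

trilinear_sample <- function(D, pts, spacing, origin) {
  d <- dim(D)
  u <- sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`)
  i0 <- pmin(pmax(floor(u[, 1]), 0), d[1] - 2); fx <- pmin(pmax(u[, 1] - i0, 0), 1)
  j0 <- pmin(pmax(floor(u[, 2]), 0), d[2] - 2); fy <- pmin(pmax(u[, 2] - j0, 0), 1)
  k0 <- pmin(pmax(floor(u[, 3]), 0), d[3] - 2); fz <- pmin(pmax(u[, 3] - k0, 0), 1)
  idx <- function(i, j, k) (i + 1) + d[1] * (j + d[2] * k)
  v000 <- D[idx(i0, j0, k0)];     v100 <- D[idx(i0 + 1, j0, k0)]
  v010 <- D[idx(i0, j0 + 1, k0)]; v110 <- D[idx(i0 + 1, j0 + 1, k0)]
  v001 <- D[idx(i0, j0, k0 + 1)]; v101 <- D[idx(i0 + 1, j0, k0 + 1)]
  v011 <- D[idx(i0, j0 + 1, k0 + 1)]; v111 <- D[idx(i0 + 1, j0 + 1, k0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# 0-based (i,j,k) index matrix of TRUE voxels, in array (column-major) order
which_ijk <- function(mask) {
  d <- dim(mask)
  lin <- which(mask) - 1L
  cbind(i = lin %% d[1],
        j = (lin %/% d[1]) %% d[2],
        k = lin %/% (d[1] * d[2]))
}

#' Assign each wall voxel the normal of its closest mesh vertex
#'
#' For every wall voxel, the nearest mesh vertex by Euclidean distance in
#' world mm is found (ties broken towards the lowest vertex id) and the
#' voxel inherits that vertex's outward unit normal.
#'
#' @param wall logical 3D array.
#' @param mesh an oriented [wall_mesh][build_wall_mesh()].
#' @return An object of class `wall_voxel_map`: data frame with 0-based
#'   voxel indices `i,j,k`, world centers `x,y,z`, unit normals
#'   `nx,ny,nz`, and `vertex_id`; plus the grid geometry and wall voxel
#'   count as attributes.
#' @export
assign_voxel_normals <- function(wall, mesh) {
  if (inherits(wall, "image_volume")) wall <- wall$data
  storage.mode(wall) <- "logical"
  ijk <- which_ijk(wall)
  if (nrow(ijk) == 0L) stop("wall mask is empty", call. = FALSE)
  ctr <- voxel_center(list(spacing = mesh$spacing, origin = mesh$origin), ijk)
  vid <- nearest_vertex_ids(mesh$vertices, ctr, cell = max(mesh$spacing))
  nrm <- mesh$vertex_normals[vid, , drop = FALSE]
  map <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                    vertex_id = vid)
  structure(map, class = c("wall_voxel_map", "data.frame"),
            spacing = mesh$spacing, origin = mesh$origin, dim3 = dim(wall))
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh a [wall_mesh][build_wall_mesh()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  vt <- cbind(mesh$vertices, mesh$vertex_normals)
  writeLines(apply(format(vt, trim = TRUE, digits = 9), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
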