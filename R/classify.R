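#' Patient-specific mitral-valve signal-intensity threshold
#'
#' The fibrosis threshold is anchored to the signal intensity of a
#' mitral-valve ROI in the water image: `threshold = c * mean(SI) + k * SD(SI)`
#' over the ROI. The defaults (`c = 1`, `k = 0`) use the MV mean itself;
#' both knobs are exposed because no single fixed rule dominates the
#' LA-LGE literature.
#'
#' @param water an [image_volume()] (water SI).
#' @param mv_roi logical 3D array, the MV ROI.
#' @param c_mult multiplier on the ROI mean (default 1).
#' @param k_sd multiplier on the ROI sample SD (default 0).
#' @return Threshold scalar in SI units.
#' @export
mv_threshold <- function(water, mv_roi, c_mult = 1, k_sd = 0) {
  if (inherits(mv_roi, "image_volume")) mv_roi <- mv_roi$data
  storage.mode(mv_roi) <- "logical"
  if (!any(mv_roi)) stop("MV ROI is empty", call. = FALSE)
  if (c_mult <= 0 || k_sd < 0)
    stop("require c_mult > 0 and k_sd >= 0", call. = FALSE)
  vals <- water$data[mv_roi]
  s <- if (length(vals) > 1) sd(vals) else 0
  c_mult * mean(vals) + k_sd * s
}

#' Fibrosis flags from a signal-intensity threshold
#'
#' A wall voxel is fibrotic iff its water SI exceeds the threshold.
#'
#' @param water an [image_volume()].
#' @param wall_map a [wall_voxel_map][assign_voxel_normals()].
#' @param threshold finite SI threshold.
#' @return Logical vector over the wall voxels of `wall_map`.
#' @export
classify_fibrosis_si <- function(water, wall_map, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  wall_si(water, wall_map) > threshold
}

wall_si <- function(water, wall_map) {
  d <- dim(water$data)
  lin <- 1 + wall_map$i + d[1] * (wall_map$j + d[2] * wall_map$k)
  water$data[lin]
}

#' Per-voxel image intensity ratio (IIR)
#'
#' IIR of a wall voxel is its water SI divided by the mean SI over the
#' blood pool — the standard normalisation that makes fixed thresholds
#' (1.2 for fibrosis, 1.32 for dense scar) transferable across patients.
#'
#' @param water an [image_volume()].
#' @param wall_map a [wall_voxel_map][assign_voxel_normals()].
#' @param blood_pool logical 3D array.
#' @return Numeric vector of IIR values over the wall voxels.
#' @export
compute_iir <- function(water, wall_map, blood_pool) {
  if (inherits(blood_pool, "image_volume")) blood_pool <- blood_pool$data
  storage.mode(blood_pool) <- "logical"
  if (!any(blood_pool)) stop("blood pool is empty", call. = FALSE)
  bp_mean <- mean(water$data[blood_pool])
  if (!is.finite(bp_mean) || bp_mean <= 0)
    stop("blood-pool mean SI must be positive", call. = FALSE)
  wall_si(water, wall_map) / bp_mean
}

#' Fibrosis flags from IIR values
#'
#' @param iir numeric vector from [compute_iir()].
#' @param tau positive IIR threshold (1.2 and 1.32 are the conventional
#'   fibrosis and dense-scar cutoffs).
#' @return Logical vector, `TRUE` where `iir > tau`.
#' @export
classify_fibrosis_iir <- function(iir, tau) {
  if (tau <= 0) stop("IIR threshold must be positive", call. = FALSE)
  iir > tau
}

#' Ray-casting parameters for EAT adjacency
#'
#' @param depth_mm outward reach of the orthogonal ray (default 6 mm).
#' @param step_mm ray sampling increment (default 0.5 mm).
#' @return A list with class `adjacency_params`.
#' @export
adjacency_params <- function(depth_mm = 6, step_mm = 0.5) {
  if (step_mm <= 0 || step_mm > depth_mm)
    stop("require 0 < step_mm <= depth_mm", call. = FALSE)
  structure(list(depth_mm = depth_mm, step_mm = step_mm),
            class = "adjacency_params")
}

#' EAT-adjacency flags by outward normal-ray casting
#'
#' For each wall voxel, points are sampled along its outward normal at
#' `step, 2*step, ..., depth` mm from the voxel center; each sample is
#' looked up in the EAT mask by nearest voxel. Samples that fall back
#' inside the wall are skipped (intramural voxel centers can sit mid-wall);
#' samples off the grid terminate the ray. The voxel is EAT-adjacent iff
#' any sample lands in EAT.
#'
#' @param wall_map a [wall_voxel_map][assign_voxel_normals()] with oriented
#'   normals.
#' @param eat logical 3D array.
#' @param params an [adjacency_params()].
#' @return Logical vector over the wall voxels.
#' @export
classify_eat_adjacent <- function(wall_map, eat, params = adjacency_params()) {
  if (inherits(eat, "image_volume")) eat <- eat$data
  storage.mode(eat) <- "logical"
  d <- attr(wall_map, "dim3")
  wall <- array(FALSE, d)
  wall[1 + wall_map$i + d[1] * (wall_map$j + d[2] * wall_map$k)] <- TRUE
  ray_adjacency(as.matrix(wall_map[, c("x", "y", "z")]),
                as.matrix(wall_map[, c("nx", "ny", "nz")]),
                eat, wall, as.integer(d),
                attr(wall_map, "spacing"), attr(wall_map, "origin"),
                params$depth_mm, params$step_mm)
}

#' Overlap flags: fibrotic AND EAT-adjacent
#'
#' @param fibrosis_flags,adjacency_flags logical vectors over one
#'   [wall_voxel_map][assign_voxel_normals()].
#' @return Logical vector, the voxelwise conjunction.
#' @export
classify_overlap <- function(fibrosis_flags, adjacency_flags) {
  if (length(fibrosis_flags) != length(adjacency_flags))
    stop("flag vectors must cover the same wall voxels", call. = FALSE)
  fibrosis_flags & adjacency_flags
}

#' Per-voxel label table for one case
#'
#' Combines the per-method fibrosis flags, the adjacency flag and the
#' overlap flags into one exportable table (CSV-ready), mirroring the
#' label-map rendering of the analysis.
#'
#' @param wall_map a [wall_voxel_map][assign_voxel_normals()].
#' @param flags named list of logical vectors (e.g. `fib_mvsi`,
#'   `fib_iir12`, `fib_iir132`, `eat_adj`, `overlap_mvsi`, ...).
#' @return A data frame with `i,j,k` and one column per flag set.
#' @export
voxel_label_table <- function(wall_map, flags) {
  stopifnot(all(vapply(flags, length, 1L) == nrow(wall_map)))
  cbind(wall_map[, c("i", "j", "k")], as.data.frame(flags))
}
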