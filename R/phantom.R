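#' Configuration for a synthetic LA phantom
#'
#' The phantom is an ellipsoidal closed wall shell (cavity = blood pool,
#' shell = intramural wall) with exterior cap-shaped EAT deposits held off
#' the epicardial surface by a configurable gap, intramural hyperenhanced
#' (fibrotic) patches placed to an exact voxel quota, and a small
#' mitral-valve ROI at the inferior pole. Signal intensities are Gaussian
#' around per-tissue means, in arbitrary SI units.
#'
#' @param dim grid shape (default 128 x 128 x 56, the acquisition footprint
#'   at desk scale).
#' @param spacing voxel spacing mm (default 1.25 x 1.25 x 2.5, the
#'   reference acquisition grid).
#' @param radii_mm cavity ellipsoid semi-axes (mm).
#' @param wall_thickness_mm shell thickness (must be >= 2x the finest
#'   spacing so the shell is watertight on the grid).
#' @param eat_coverage target fraction of the wall surface subtended by EAT
#'   deposits, in `[0, 1]`.
#' @param n_eat_deposits number of cap deposits sharing the coverage.
#' @param eat_thickness_mm radial thickness of the EAT deposits.
#' @param eat_gap_mm radial offset of EAT from the epicardial surface (must
#'   stay below the adjacency depth for rays to reach it).
#' @param eat_deposit_dirs optional K x 3 matrix of unit directions pinning
#'   the deposit centers (default: random, seeded).
#' @param fibrosis_fraction target fraction of wall voxels hyperenhanced,
#'   in `[0, 1]` (placement is quota-exact).
#' @param n_fibrosis_patches number of fibrotic patch centers.
#' @param colocalization in `[-1, 1]`: 0 places fibrosis independently of
#'   EAT, 1 centers every patch under an EAT deposit footprint, -1 avoids
#'   the footprint.
#' @param si_levels named numeric: `blood`, `wall`, `fibrosis`, `mv`,
#'   `eat`, `background` tissue means and the shared per-voxel `sd`
#'   (arbitrary SI units). `fibrosis` must exceed `wall`.
#' @param seed integer RNG seed; the phantom is deterministic given it.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(128L, 128L, 56L),
                           spacing = c(1.25, 1.25, 2.5),
                           radii_mm = c(34, 29, 31),
                           wall_thickness_mm = 4,
                           eat_coverage = 0.15,
                           n_eat_deposits = 3,
                           eat_thickness_mm = 3,
                           eat_gap_mm = 2,
                           eat_deposit_dirs = NULL,
                           fibrosis_fraction = 0.08,
                           n_fibrosis_patches = 8,
                           colocalization = 0,
                           si_levels = c(blood = 100, wall = 60, fibrosis = 150,
                                         mv = 80, eat = 40, background = 30,
                                         sd = 5),
                           seed = 1L) {
  cfg <- as.list(environment())
  if (eat_coverage < 0 || eat_coverage > 1 ||
      fibrosis_fraction < 0 || fibrosis_fraction > 1)
    stop("coverage and fibrosis fractions must lie in [0, 1]", call. = FALSE)
  if (abs(colocalization) > 1)
    stop("colocalization must lie in [-1, 1]", call. = FALSE)
  if (si_levels[["fibrosis"]] <= si_levels[["wall"]])
    stop("fibrotic SI mean must exceed healthy wall SI mean", call. = FALSE)
  if (wall_thickness_mm < 2 * min(spacing))
    stop("wall thickness must be >= 2x the finest spacing for a watertight shell",
         call. = FALSE)
  half_extent <- (dim - 1) / 2 * spacing
  reach <- radii_mm + wall_thickness_mm + eat_gap_mm + eat_thickness_mm + 2 * spacing
  if (any(reach > half_extent))
    stop("phantom geometry does not fit the grid (need >= ",
         paste(round(2 * reach / spacing + 1), collapse = " x "), " voxels)",
         call. = FALSE)
  if (n_eat_deposits >= 1 && eat_coverage / n_eat_deposits > 1)
    stop("per-deposit coverage exceeds a hemisphere pair", call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipsoid_rho2 <- function(xs, ys, zs, semi) {
  outer(outer((xs / semi[1])^2, (ys / semi[2])^2, `+`), (zs / semi[3])^2, `+`)
}

#' Generate a synthetic LA phantom with ground truth
#'
#' @param config a [phantom_config()].
#' @return A list of class `la_phantom`: `volumes` (named list with
#'   `water`), `masks` (a [label_masks()]), `truth` (designed and realized
#'   fractions, fibrosis voxel set, EAT-footprint wall voxel set, deposit
#'   geometry) and `config`.
#' @export
generate_la_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    d <- as.integer(config$dim); sp <- config$spacing
    ctr <- (d - 1) / 2 * sp
    xs <- (0:(d[1] - 1)) * sp[1] - ctr[1]
    ys <- (0:(d[2] - 1)) * sp[2] - ctr[2]
    zs <- (0:(d[3] - 1)) * sp[3] - ctr[3]
    r_in <- config$radii_mm
    r_out <- r_in + config$wall_thickness_mm
    r_gap <- r_out + config$eat_gap_mm
    r_fat <- r_gap + config$eat_thickness_mm

    blood_pool <- ellipsoid_rho2(xs, ys, zs, r_in) < 1
    wall <- !blood_pool & ellipsoid_rho2(xs, ys, zs, r_out) <= 1
    eat_shell <- ellipsoid_rho2(xs, ys, zs, r_gap) > 1 &
      ellipsoid_rho2(xs, ys, zs, r_fat) <= 1

    # cap deposits: unit directions + shared half-angle from the coverage
    K <- if (config$eat_coverage > 0) config$n_eat_deposits else 0L
    cos_half <- if (K > 0) 1 - 2 * config$eat_coverage / K else 1
    dirs <- config$eat_deposit_dirs
    if (K > 0 && is.null(dirs)) dirs <- draw_cap_dirs(K, cos_half)
    in_cap <- function(mask) {
      if (K == 0) return(array(FALSE, d))
      ijk <- which_ijk(mask)
      P <- sweep(sweep(ijk, 2, sp, `*`), 2, ctr, `-`)
      u <- P / pmax(sqrt(rowSums(P^2)), 1e-9)
      hit <- rep(FALSE, nrow(u))
      for (q in seq_len(K))
        hit <- hit | (u %*% dirs[q, ])[, 1] > cos_half
      out <- array(FALSE, d)
      out[which(mask)[hit]] <- TRUE
      out
    }
    eat <- eat_shell & in_cap(eat_shell)
    eat_footprint <- wall & in_cap(wall)   # ground-truth adjacency set

    # MV ROI: 4 mm ball just below the inferior pole, outside all other masks
    mv_ctr <- c(0, 0, -(r_out[3] + 2 + 4))
    mv <- outer(outer(xs^2, ys^2, `+`), (zs - mv_ctr[3])^2, `+`) <= 16 &
      !wall & !blood_pool & !eat

    # fibrosis: patch centers by colocalization rule, grown to exact quota
    wall_lin <- which(wall)
    n_wall <- length(wall_lin)
    n_fib <- round(config$fibrosis_fraction * n_wall)
    fib_lin <- integer(0)
    centers_lin <- integer(0)
    if (n_fib > 0) {
      wall_xyz <- sweep(sweep(which_ijk(wall), 2, sp, `*`), 2, ctr, `-`)
      under <- eat_footprint[wall_lin]
      centers <- draw_patch_centers(config$n_fibrosis_patches,
                                    config$colocalization, under,
                                    wall_xyz, min_sep = 15)
      dmin <- rep(Inf, n_wall)
      for (cidx in centers) {
        dd <- (wall_xyz[, 1] - wall_xyz[cidx, 1])^2 +
              (wall_xyz[, 2] - wall_xyz[cidx, 2])^2 +
              (wall_xyz[, 3] - wall_xyz[cidx, 3])^2
        dmin <- pmin(dmin, dd)
      }
      fib_lin <- wall_lin[order(dmin, wall_lin)[seq_len(n_fib)]]
      centers_lin <- wall_lin[centers]
    }
    fibrosis <- array(FALSE, d)
    fibrosis[fib_lin] <- TRUE

    si <- config$si_levels
    water <- array(si[["background"]], d)
    water[eat] <- si[["eat"]]
    water[blood_pool] <- si[["blood"]]
    water[wall] <- si[["wall"]]
    water[fibrosis] <- si[["fibrosis"]]
    water[mv] <- si[["mv"]]
    if (si[["sd"]] > 0)
      water <- water + array(rnorm(prod(d), 0, si[["sd"]]), d)

    masks <- label_masks(wall, blood_pool, eat, mv_roi = mv)
    truth <- list(
      fibrosis_lin = fib_lin,
      patch_centers_lin = centers_lin,
      eat_footprint_lin = which(eat_footprint),
      designed = list(fibrosis_fraction = config$fibrosis_fraction,
                      eat_coverage = config$eat_coverage,
                      colocalization = config$colocalization),
      realized = list(
        fibrosis_fraction = if (n_wall) n_fib / n_wall else 0,
        eat_adjacent_fraction = if (n_wall) sum(eat_footprint) / n_wall else 0),
      cap_dirs = dirs, cap_cos_half = cos_half, center_mm = ctr)
    structure(list(volumes = list(water = image_volume(water, sp)),
                   masks = masks, truth = truth, config = config),
              class = "la_phantom")
  })
}

#' @export
print.la_phantom <- function(x, ...) {
  cat("<la_phantom> grid ", paste(x$config$dim, collapse = " x "),
      ", designed fibrosis ", x$truth$designed$fibrosis_fraction,
      ", EAT coverage ", x$truth$designed$eat_coverage,
      " (realized adjacency ",
      format(x$truth$realized$eat_adjacent_fraction, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

draw_cap_dirs <- function(K, cos_half, tries = 200) {
  sep <- 2 * acos(min(1, cos_half))  # keep caps from overlapping when possible
  for (t in seq_len(tries)) {
    m <- matrix(rnorm(3 * K), K, 3)
    m <- m / sqrt(rowSums(m^2))
    ok <- TRUE
    if (K > 1) {
      ang <- matrix(acos(pmin(1, pmax(-1, as.numeric(tcrossprod(m))))), K, K)
      diag(ang) <- Inf
      ok <- min(ang) > sep
    }
    if (ok) return(m)
  }
  m  # best effort: dense coverage makes full separation impossible
}

draw_patch_centers <- function(n_patches, coloc, under_eat, wall_xyz,
                               min_sep = 15, tries = 50) {
  n <- nrow(wall_xyz)
  pool_pref <- if (coloc >= 0) which(under_eat) else which(!under_eat)
  centers <- integer(0)
  for (p in seq_len(n_patches)) {
    for (t in seq_len(tries)) {
      use_pref <- length(pool_pref) > 0 && runif(1) < abs(coloc)
      cand <- if (use_pref) pool_pref[sample.int(length(pool_pref), 1)]
              else sample.int(n, 1)
      if (!length(centers)) { sepok <- TRUE } else {
        dd <- sqrt((wall_xyz[centers, 1] - wall_xyz[cand, 1])^2 +
                   (wall_xyz[centers, 2] - wall_xyz[cand, 2])^2 +
                   (wall_xyz[centers, 3] - wall_xyz[cand, 3])^2)
        sepok <- min(dd) > min_sep
      }
      if (sepok || t == tries) { centers <- c(centers, cand); break }
    }
  }
  centers
}
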