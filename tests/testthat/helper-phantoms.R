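# Shared phantom builders. Small grids keep single tests fast; the
# spherical configurations give analytic oracles (cap solid angle, sphere
# area/volume).

# spherical shell r = 30 mm on an isotropic grid with one polar EAT cap of
# half-angle 60 deg at 2 mm gap: ground-truth adjacent fraction
# (1 - cos 60)/2 = 0.25
sphere_cap_config <- function(spacing = 1, seed = 1, noise_sd = 0,
                              fibrosis_fraction = 0.2) {
  n <- ceiling(84 / spacing)
  phantom_config(
    dim = rep(n, 3), spacing = rep(spacing, 3), radii_mm = c(30, 30, 30),
    wall_thickness_mm = 3, eat_coverage = 0.25, n_eat_deposits = 1,
    eat_deposit_dirs = matrix(c(0, 0, 1), 1), eat_gap_mm = 2,
    eat_thickness_mm = 3, fibrosis_fraction = fibrosis_fraction,
    si_levels = c(blood = 100, wall = 60, fibrosis = 150, mv = 80,
                  eat = 40, background = 30, sd = noise_sd),
    seed = seed)
}

# small anisotropic-grid phantom for fast unit tests (~3k wall voxels)
tiny_config <- function(seed = 1, ...) {
  args <- list(dim = c(48L, 48L, 26L), spacing = c(1.25, 1.25, 2.5),
               radii_mm = c(16, 14, 12), wall_thickness_mm = 4,
               eat_coverage = 0.2, n_eat_deposits = 2,
               fibrosis_fraction = 0.1, seed = seed)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# digital ball mask of radius r mm on an isotropic grid
digital_ball <- function(r = 30, spacing = 1) {
  n <- ceiling((2 * r + 6) / spacing)
  ctr <- (n - 1) / 2 * spacing
  xs <- (0:(n - 1)) * spacing - ctr
  outer(outer(xs^2, xs^2, `+`), xs^2, `+`) <= r^2
}

# small closed spherical shell mask (isotropic) for mesh unit tests
shell_mask <- function(r_in = 10, r_out = 13, n = 32, spacing = 1) {
  ctr <- (n - 1) / 2 * spacing
  xs <- (0:(n - 1)) * spacing - ctr
  r2 <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`)
  list(wall = r2 > r_in^2 & r2 <= r_out^2, blood = r2 <= r_in^2,
       spacing = rep(spacing, 3))
}
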