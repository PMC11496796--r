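#' Configuration for a synthetic cohort
#'
#' Draws one phantom per subject from per-AF-group distributions. The
#' defaults emulate the cohort structure the analysis targets: group sizes
#' 9/18/10/14 (non-AF, paroxysmal, persistent, permanent); LA volume and
#' EAT coverage rising from paroxysmal to permanent; fibrosis fraction flat
#' across groups; colocalization flat at 0 (fibrosis placed independently
#' of EAT, mirroring the null overlap structure); covariates (height,
#' weight, LVEF) at clinically typical levels.
#'
#' @param group_n integer length-4, subjects per group in the order
#'   non-AF, paroxysmal, persistent, permanent.
#' @param la_volume_ml_mean,la_volume_ml_sd per-group target LA volume (mL).
#' @param eat_coverage_mean,eat_coverage_sd per-group EAT wall coverage.
#' @param fibrosis_fraction_mean,fibrosis_fraction_sd per-group fibrotic
#'   wall-voxel fraction.
#' @param colocalization_mean per-group EAT-fibrosis colocalization.
#' @param lvef_mean,lvef_sd per-group LVEF (%).
#' @param height_cm_mean,height_cm_sd,weight_kg_mean,weight_kg_sd covariate
#'   distributions (shared across groups).
#' @param base_config a [phantom_config()] supplying grid geometry, SI
#'   levels and all per-phantom settings not drawn per subject.
#' @param seed integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_n = c(9L, 18L, 10L, 14L),
                          la_volume_ml_mean = c(113, 124, 159, 188),
                          la_volume_ml_sd = c(40, 35, 38, 54),
                          eat_coverage_mean = c(0.10, 0.10, 0.18, 0.25),
                          eat_coverage_sd = rep(0.05, 4),
                          fibrosis_fraction_mean = c(0.09, 0.07, 0.08, 0.075),
                          fibrosis_fraction_sd = rep(0.04, 4),
                          colocalization_mean = rep(0, 4),
                          lvef_mean = c(52, 60, 52, 48),
                          lvef_sd = c(17, 7, 10, 12),
                          height_cm_mean = 172, height_cm_sd = 10,
                          weight_kg_mean = 82, weight_kg_sd = 13,
                          base_config = phantom_config(),
                          seed = 1L) {
  cfg <- as.list(environment())
  if (length(group_n) != 4L || any(group_n < 0))
    stop("group_n must be four non-negative counts", call. = FALSE)
  if (sum(group_n > 0) < 2L)
    stop("at least two groups must be non-empty", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic cohort of LA phantoms with covariates
#'
#' Per subject, a [phantom_config()] is drawn from the group distributions
#' (LA volume acts through isotropic scaling of the cavity ellipsoid) and a
#' phantom generated from a subject seed derived from the master seed.
#' Reproducible: the same `config` yields the identical cohort.
#'
#' @param config a [cohort_config()].
#' @return A list of class `la_cohort_sim`: `cases` (list of
#'   [la_phantom][generate_la_phantom()]), `covariates` (data frame with
#'   `subject_id`, `group`, `height_cm`, `weight_kg`, `lvef_pct`), and
#'   `truth` (per-subject designed parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$group_n)
  if (n_total == 0L) stop("empty cohort", call. = FALSE)
  groups <- rep(af_levels(), config$group_n)
  base <- config$base_config
  v0 <- 4 / 3 * pi * prod(base$radii_mm) / 1000  # cavity volume of the base ellipsoid, mL

  with_seed(config$seed, {
    subj_seed <- sample.int(.Machine$integer.max %/% 2L, n_total)
    gi <- match(groups, af_levels())
    la_target <- rtrunc_norm(n_total, config$la_volume_ml_mean[gi],
                             config$la_volume_ml_sd[gi], 60, 320)
    eatc <- rtrunc_norm(n_total, config$eat_coverage_mean[gi],
                        config$eat_coverage_sd[gi], 0.02, 0.5)
    fibf <- rtrunc_norm(n_total, config$fibrosis_fraction_mean[gi],
                        config$fibrosis_fraction_sd[gi], 0.005, 0.3)
    coloc <- pmin(pmax(config$colocalization_mean[gi], -1), 1)
    height <- rtrunc_norm(n_total, config$height_cm_mean, config$height_cm_sd, 145, 205)
    weight <- rtrunc_norm(n_total, config$weight_kg_mean, config$weight_kg_sd, 45, 140)
    lvef <- rtrunc_norm(n_total, config$lvef_mean[gi], config$lvef_sd[gi], 15, 75)

    cases <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      scale <- (la_target[s] / v0)^(1 / 3)
      args <- unclass(base)
      args$radii_mm <- base$radii_mm * scale
      args$eat_coverage <- eatc[s]
      args$fibrosis_fraction <- fibf[s]
      args$colocalization <- coloc[s]
      args$seed <- subj_seed[s]
      pc <- do.call(phantom_config, args)  # re-validates drawn geometry
      cases[[s]] <- generate_la_phantom(pc)
    }
    covariates <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_total)),
      group = factor(groups, levels = af_levels(), ordered = TRUE),
      height_cm = height, weight_kg = weight, lvef_pct = lvef,
      stringsAsFactors = FALSE)
    truth <- data.frame(subject_id = covariates$subject_id,
                        group = covariates$group,
                        la_volume_target_ml = la_target,
                        eat_coverage = eatc, fibrosis_fraction = fibf,
                        colocalization = coloc, seed = subj_seed)
    structure(list(cases = cases, covariates = covariates, truth = truth,
                   config = config),
              class = "la_cohort_sim")
  })
}

#' @export
print.la_cohort_sim <- function(x, ...) {
  cat("<la_cohort_sim> ", length(x$cases), " subjects (",
      paste(x$config$group_n, collapse = "/"), " per AF group)\n", sep = "")
  invisible(x)
}
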