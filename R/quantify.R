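#' LA volume by transversal slice-area summation
#'
#' Sums the outlined LA area over the transversal stack: per slice,
#' foreground voxel count times in-plane pixel area, times slice thickness.
#' Because the slices partition the mask this equals voxel count times
#' voxel volume exactly; the summation form mirrors how the measurement is
#' defined on the acquisition stack.
#'
#' @param la_cavity logical 3D array (cavity = blood pool + wall by
#'   default upstream).
#' @param spacing voxel spacing in mm.
#' @param stack_axis axis of the transversal stack (default 3).
#' @return Volume in mL.
#' @export
la_volume_slice_sum <- function(la_cavity, spacing, stack_axis = 3) {
  if (inherits(la_cavity, "image_volume")) {
    spacing <- la_cavity$spacing; la_cavity <- la_cavity$data
  }
  storage.mode(la_cavity) <- "logical"
  if (!any(la_cavity)) {
    warning("LA cavity mask is empty; volume is 0")
    return(0)
  }
  inplane <- prod(spacing[-stack_axis])
  slice_counts <- apply(la_cavity, stack_axis, sum)
  sum(slice_counts * inplane) * spacing[stack_axis] / 1000
}

#' EAT volume by voxel counting
#'
#' @param eat logical 3D array (EAT mask from the fat image).
#' @param spacing voxel spacing in mm.
#' @return Volume in mL.
#' @export
eat_volume <- function(eat, spacing) {
  if (inherits(eat, "image_volume")) { spacing <- eat$spacing; eat <- eat$data }
  sum(eat != 0) * prod(spacing) / 1000
}

#' Single-sided wall surface area from the mesh
#'
#' The wall isosurface of a thin shell has two sheets (endocardial and
#' epicardial); half the total triangle area is the single-sided wall
#' surface used as the denominator for relative areas.
#'
#' @param mesh a [wall_mesh][build_wall_mesh()].
#' @return Area in cm^2.
#' @export
wall_surface_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces", call. = FALSE)
  sum(face_areas(mesh$vertices, mesh$faces)) / 2 / 100
}

#' Relative area of a flagged wall-voxel set
#'
#' @param flags logical vector over the wall voxels.
#' @return Percent of the wall (0-100).
#' @export
relative_area <- function(flags) {
  if (length(flags) == 0L) stop("wall voxel set is empty", call. = FALSE)
  100 * sum(flags) / length(flags)
}

#' Absolute area of a flagged wall-voxel set
#'
#' Converts a wall-voxel fraction into cm^2 of wall surface, so that
#' `absolute / total == relative / 100` holds exactly.
#'
#' @param flags logical vector over the wall voxels.
#' @param total_area_cm2 single-sided wall area from [wall_surface_area()].
#' @return Area in cm^2.
#' @export
absolute_area <- function(flags, total_area_cm2) {
  if (total_area_cm2 < 0) stop("total area must be >= 0", call. = FALSE)
  relative_area(flags) / 100 * total_area_cm2
}

#' Body surface area
#'
#' Mosteller by default: `sqrt(height_cm * weight_kg / 3600)`; Du Bois
#' available as an alternative.
#'
#' @param height_cm,weight_kg positive scalars.
#' @param formula `"mosteller"` (default) or `"dubois"`.
#' @return BSA in m^2.
#' @export
bsa <- function(height_cm, weight_kg, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  switch(formula,
         mosteller = sqrt(height_cm * weight_kg / 3600),
         dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
}

#' Assemble the per-subject metric record
#'
#' Collects the quantified imaging metrics (per fibrosis method) and the
#' clinical covariates into one record; indexed variants are absolute
#' values divided by BSA. Missing covariates leave the indexed fields `NA`
#' and flag the record.
#'
#' @param subject_id identifier.
#' @param group AF type, one of `"non-AF"`, `"paroxysmal"`, `"persistent"`,
#'   `"permanent"` (or `NA`).
#' @param la_volume_ml,eat_volume_ml,wall_area_cm2 scalar metrics.
#' @param eat_adjacent_flags logical vector over wall voxels.
#' @param fibrosis_flags named list of logical vectors, one per method
#'   (e.g. `mvsi`, `iir12`, `iir132`).
#' @param covariates optional list/row with `height_cm`, `weight_kg`,
#'   `lvef_pct`.
#' @return An object of class `subject_record` (a one-row data frame).
#' @export
build_subject_record <- function(subject_id, group, la_volume_ml,
                                 eat_volume_ml, wall_area_cm2,
                                 eat_adjacent_flags, fibrosis_flags,
                                 covariates = NULL) {
  stopifnot(is.list(fibrosis_flags), length(fibrosis_flags) >= 1)
  eat_pct <- relative_area(eat_adjacent_flags)
  rec <- data.frame(
    subject_id = subject_id,
    group = factor(group, levels = af_levels(), ordered = TRUE),
    la_volume_ml = la_volume_ml,
    eat_volume_ml = eat_volume_ml,
    wall_area_cm2 = wall_area_cm2,
    eat_area_pct = eat_pct,
    eat_area_cm2 = eat_pct / 100 * wall_area_cm2,
    stringsAsFactors = FALSE)
  for (m in names(fibrosis_flags)) {
    fib <- fibrosis_flags[[m]]
    ovl <- classify_overlap(fib, eat_adjacent_flags)
    rec[[paste0("fibrosis_pct_", m)]] <- relative_area(fib)
    rec[[paste0("fibrosis_area_cm2_", m)]] <- absolute_area(fib, wall_area_cm2)
    rec[[paste0("overlap_pct_", m)]] <- relative_area(ovl)
    rec[[paste0("overlap_area_cm2_", m)]] <- absolute_area(ovl, wall_area_cm2)
  }
  rec$bsa_m2 <- NA_real_
  rec$lvef_pct <- NA_real_
  rec$height_cm <- NA_real_
  rec$weight_kg <- NA_real_
  if (!is.null(covariates) &&
      !is.null(covariates$height_cm) && !is.null(covariates$weight_kg) &&
      is.finite(covariates$height_cm) && is.finite(covariates$weight_kg)) {
    rec$height_cm <- covariates$height_cm
    rec$weight_kg <- covariates$weight_kg
    rec$bsa_m2 <- bsa(covariates$height_cm, covariates$weight_kg)
    rec$la_volume_index <- rec$la_volume_ml / rec$bsa_m2
    rec$eat_volume_index <- rec$eat_volume_ml / rec$bsa_m2
    rec$eat_area_index <- rec$eat_area_cm2 / rec$bsa_m2
  } else {
    rec$la_volume_index <- NA_real_
    rec$eat_volume_index <- NA_real_
    rec$eat_area_index <- NA_real_
    attr(rec, "missing_covariates") <- TRUE
  }
  if (!is.null(covariates) && !is.null(covariates$lvef_pct))
    rec$lvef_pct <- covariates$lvef_pct
  class(rec) <- c("subject_record", "data.frame")
  rec
}

af_levels <- function() c("non-AF", "paroxysmal", "persistent", "permanent")

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, " [", as.character(x$group), "]\n",
      sep = "")
  cat(sprintf("  LA volume %.1f mL | EAT %.1f mL | wall %.1f cm^2 | EAT-adjacent %.1f%%\n",
              x$la_volume_ml, x$eat_volume_ml, x$wall_area_cm2, x$eat_area_pct))
  for (m in sub("^fibrosis_pct_", "", grep("^fibrosis_pct_", names(x), value = TRUE)))
    cat(sprintf("  [%s] fibrosis %.2f%% (%.2f cm^2), overlap %.2f%% (%.2f cm^2)\n",
                m, x[[paste0("fibrosis_pct_", m)]], x[[paste0("fibrosis_area_cm2_", m)]],
                x[[paste0("overlap_pct_", m)]], x[[paste0("overlap_area_cm2_", m)]]))
  invisible(x)
}
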