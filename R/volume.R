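#' 3D scalar image volume on an axis-aligned grid
#'
#' Container for a scalar volume (water signal intensity or any channel)
#' together with its grid geometry. Voxel indices are 0-based in the world
#' mapping: the center of voxel `(i, j, k)` lies at
#' `origin + (i * sx, j * sy, k * sz)` mm. Only axis-aligned grids are
#' supported; the third axis is the transversal stack axis by convention.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world mm of the center of voxel (0,0,0).
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' iv <- image_volume(array(0, c(4, 4, 2)), spacing = c(1.25, 1.25, 2.5))
#' voxel_center(iv, c(1, 1, 1))
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' World coordinates of voxel centers
#'
#' @param vol an `image_volume` (or any object with `spacing`/`origin`).
#' @param ijk integer matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_center <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Read a NIfTI-1 scalar volume
#'
#' Reads a 3D NIfTI file into an [image_volume()]. Grid geometry is taken
#' from the header xform; only axis-aligned headers (diagonal rotation part
#' with positive scales) are accepted — oblique acquisitions must be
#' resampled upstream.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- structure(as.vector(arr), dim = dim(arr))  # drop header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    dim(arr) <- dim(arr)[1:3]
  } else if (length(dim(arr)) != 3L) {
    stop("`", path, "` is not a 3D scalar volume (found ",
         length(dim(arr)), " dimensions)", call. = FALSE)
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`", path, "`: non-positive voxel spacing in header", call. = FALSE)
  offdiag <- abs(rot) - diag(abs(diag(rot)))
  if (max(abs(offdiag)) > 1e-3 * max(spacing))
    stop("`", path, "`: oblique orientation not supported; resample to an ",
         "axis-aligned grid first", call. = FALSE)
  if (any(diag(rot) < 0)) {
    # NIfTI RAS flips: our own writer emits positive diagonals; accept flips
    # by reorienting data so the stored array is in +x/+y/+z order.
    for (ax in which(diag(rot) < 0)) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
      arr <- do.call(`[`, c(list(arr), idx, drop = FALSE))
      xf[ax, 4] <- xf[ax, 4] + rot[ax, ax] * (dim(arr)[ax] - 1)
    }
  }
  image_volume(arr, spacing = spacing, origin = xf[1:3, 4])
}

#' Write a volume or binary mask as NIfTI-1
#'
#' Masks (logical arrays) are stored as unsigned 8-bit; scalar volumes as
#' 32-bit float. The sform encodes the axis-aligned spacing and origin.
#'
#' @param vol an [image_volume()], or a logical/numeric 3D array (then
#'   `spacing` and `origin` must be supplied).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing,origin grid geometry when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL, origin = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data; spacing <- vol$spacing; origin <- vol$origin
  } else {
    arr <- vol
    if (is.null(spacing) || is.null(origin))
      stop("supply `spacing` and `origin` when writing a bare array", call. = FALSE)
  }
  is_mask <- is.logical(arr) || all(arr %in% c(0, 1))
  storage <- if (is_mask) "uint8" else "float"
  arr <- array(as.numeric(arr), dim(arr))
  img <- RNifti::asNifti(arr, datatype = storage)
  xf <- diag(4)
  xf[1, 1] <- spacing[1]; xf[2, 2] <- spacing[2]; xf[3, 3] <- spacing[3]
  xf[1:3, 4] <- origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Co-registered segmentation masks of one LA case
#'
#' Bundles the binary masks the analysis needs: the intramural wall, the
#' blood pool it encloses, the exterior EAT, the mitral-valve ROI used for
#' the patient-specific fibrosis threshold, and the LA cavity used for
#' slice-summation volume (defaults to blood pool + wall).
#'
#' @param wall,blood_pool,eat logical 3D arrays on one grid.
#' @param mv_roi optional logical array (required for the MV-SI fibrosis
#'   method).
#' @param la_cavity optional logical array; default `wall | blood_pool`.
#' @return An object of class `label_masks`.
#' @export
label_masks <- function(wall, blood_pool, eat, mv_roi = NULL, la_cavity = NULL) {
  as_mask <- function(m) {
    if (is.null(m)) return(NULL)
    if (inherits(m, "image_volume")) m <- m$data
    storage.mode(m) <- "logical"
    m
  }
  wall <- as_mask(wall); blood_pool <- as_mask(blood_pool); eat <- as_mask(eat)
  mv_roi <- as_mask(mv_roi); la_cavity <- as_mask(la_cavity)
  if (is.null(la_cavity)) la_cavity <- wall | blood_pool
  structure(list(wall = wall, blood_pool = blood_pool, eat = eat,
                 mv_roi = mv_roi, la_cavity = la_cavity),
            class = "label_masks")
}

#' Validate a case before analysis
#'
#' Checks grid congruence of all volumes and masks and the mask invariants:
#' wall and blood pool disjoint, EAT exterior to the wall, wall a single
#' 26-connected component enclosing the blood pool, MV ROI nonempty when
#' present.
#'
#' @param volumes named list of [image_volume()] (must contain `water`).
#' @param masks a [label_masks()].
#' @param require_mv_roi if `TRUE`, a nonempty `mv_roi` is required.
#' @param stop_on_error if `TRUE` (default) violations raise one error
#'   naming each failed invariant; if `FALSE` a character vector of
#'   violations is returned (empty when valid).
#' @return A validated case (class `la_case`: the volumes, masks and grid
#'   geometry), or a character vector of violations.
#' @export
validate_case <- function(volumes, masks, require_mv_roi = TRUE,
                          stop_on_error = TRUE) {
  problems <- character()
  if (!is.list(volumes) || is.null(volumes$water))
    problems <- c(problems, "volumes must include a `water` image_volume")
  ref <- volumes$water
  if (inherits(ref, "image_volume")) {
    d0 <- dim(ref$data)
    for (nm in names(volumes)) {
      v <- volumes[[nm]]
      if (!inherits(v, "image_volume")) {
        problems <- c(problems, sprintf("volume `%s` is not an image_volume", nm))
        next
      }
      if (!identical(dim(v$data), d0))
        problems <- c(problems, sprintf("volume `%s`: grid shape differs from `water`", nm))
      if (max(abs(v$spacing - ref$spacing)) > 1e-6 ||
          max(abs(v$origin - ref$origin)) > 1e-6)
        problems <- c(problems, sprintf("volume `%s`: spacing/origin differ from `water`", nm))
    }
    for (nm in c("wall", "blood_pool", "eat", "mv_roi", "la_cavity")) {
      m <- masks[[nm]]
      if (is.null(m)) next
      if (!identical(dim(m), d0))
        problems <- c(problems, sprintf("mask `%s`: grid shape differs from volumes", nm))
    }
  }
  if (!length(problems)) {
    if (any(masks$wall & masks$blood_pool))
      problems <- c(problems, "wall ∩ blood_pool must be empty")
    if (any(masks$eat & masks$wall))
      problems <- c(problems, "eat ∩ wall must be empty (EAT is exterior to the wall)")
    if (!any(masks$wall)) {
      problems <- c(problems, "wall mask is empty")
    } else {
      lab <- label_components26(masks$wall)
      if (max(lab) > 1L)
        problems <- c(problems, sprintf(
          "wall must be a single 26-connected component (found %d)", max(lab)))
      outside <- reachable_from_border(masks$wall)
      if (any(masks$blood_pool & outside))
        problems <- c(problems, "wall does not enclose the blood pool")
    }
    if (require_mv_roi && (is.null(masks$mv_roi) || !any(masks$mv_roi)))
      problems <- c(problems, "mv_roi is empty but the MV-threshold fibrosis method was requested")
  }
  if (length(problems)) {
    if (stop_on_error)
      stop("case validation failed:\n  - ", paste(problems, collapse = "\n  - "),
           call. = FALSE)
    return(problems)
  }
  if (!stop_on_error) return(character())
  structure(list(volumes = volumes, masks = masks,
                 spacing = ref$spacing, origin = ref$origin),
            class = "la_case")
}

#' @export
print.la_case <- function(x, ...) {
  d <- dim(x$volumes$water$data)
  cat("<la_case> grid ", paste(d, collapse = " x "), ", spacing ",
      paste(format(x$spacing), collapse = " x "), " mm\n",
      "  wall voxels: ", sum(x$masks$wall),
      "; blood pool: ", sum(x$masks$blood_pool),
      "; EAT: ", sum(x$masks$eat), "\n", sep = "")
  invisible(x)
}
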