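# Field-size extraction from a 3D dose distribution.
#
# The field-area parameter F_U is defined as the average of the areas
# inside the 50% isodose on the coronal and sagittal planes through the
# isocenter.  Areas are measured by counting plane pixels at or above the
# threshold (inclusive, no sub-pixel contouring); the plane is the voxel
# slab nearest the isocenter coordinate, a documented half-voxel bias.

# model-frame axis held fixed by each named plane: coronal fixes the
# anterior-posterior (x) axis, sagittal the left-right (y) axis.
.plane_fixed_axis <- c(coronal = 1L, sagittal = 2L)

#' Area inside an isodose contour on a plane through the isocenter
#'
#' @param dose a [dose_grid()] covering the isocenter.
#' @param frame an [isocenter_frame()].
#' @param orientation `"coronal"` or `"sagittal"`.
#' @param fraction isodose fraction relative to the interpolated isocenter
#'   dose (default 0.5).
#' @return Area in cm^2.  Zero pixels above threshold return 0 with a
#'   warning.
#' @export
plane_isodose_area <- function(dose, frame, orientation = c("coronal", "sagittal"),
                               fraction = 0.5) {
  stopifnot(inherits(dose, "dose_grid"), inherits(frame, "isocenter_frame"))
  orientation <- match.arg(orientation)
  d_iso <- interp_at_point(dose, frame$isocenter)
  if (!is.finite(d_iso) || d_iso <= 0)
    .stopf("invalid input: isocenter dose must be > 0 (got %g)", d_iso)
  model_axis <- .plane_fixed_axis[[orientation]]
  grid_axis <- abs(frame$axis_map[model_axis])
  d <- dim(dose$values)
  # voxel slab nearest the isocenter along the fixed axis
  fi <- (frame$isocenter[grid_axis] - dose$origin[grid_axis]) /
    dose$spacing[grid_axis] + 1
  if (fi < 0.5 || fi > d[grid_axis] + 0.5)
    .stopf("invalid input: isocenter outside the grid along axis %d", grid_axis)
  slab <- min(max(round(fi), 1L), d[grid_axis])
  idx <- lapply(seq_len(3L), function(a) if (a == grid_axis) slab else seq_len(d[a]))
  plane <- dose$values[idx[[1]], idx[[2]], idx[[3]]]
  pixel_area <- prod(dose$spacing[-grid_axis])
  n_in <- sum(plane >= fraction * d_iso, na.rm = TRUE)
  if (n_in == 0L)
    warning(sprintf("no %s-plane pixels at or above the %g%% isodose",
                    orientation, 100 * fraction), call. = FALSE)
  n_in * pixel_area
}

#' Treatment field area from the 50% isodose
#'
#' The arithmetic mean of the coronal and sagittal 50\% isodose areas at
#' the isocenter level -- the field-size parameter the dose model takes.
#'
#' @inheritParams plane_isodose_area
#' @return A list with `coronal`, `sagittal`, `F_U` (their mean, cm^2) and
#'   `F` (the ratio to the reference area).
#' @param F_R reference field area, cm^2.
#' @export
field_area <- function(dose, frame, fraction = 0.5,
                       F_R = .peridose_defaults$F_R) {
  cor <- plane_isodose_area(dose, frame, "coronal", fraction)
  sag <- plane_isodose_area(dose, frame, "sagittal", fraction)
  F_U <- (cor + sag) / 2
  list(coronal = cor, sagittal = sag, F_U = F_U, F = F_U / F_R)
}

#' Field area from 1D profile widths at 50%
#'
#' Alternative recipe: the product of the full widths at half the
#' isocenter dose of the two 1D profiles through the isocenter on the
#' transversal-plane axes perpendicular to the beam axis (left-right and
#' craniocaudal).  Widths are measured between the outermost profile
#' samples at or above threshold, inclusive of their voxel extent.  The
#' 50\% isodose-area recipe ([field_area()]) is the default elsewhere.
#'
#' @inheritParams plane_isodose_area
#' @return A list with `width_y`, `width_z` (cm) and `F_U` (cm^2).
#' @export
field_area_profile <- function(dose, frame, fraction = 0.5) {
  stopifnot(inherits(dose, "dose_grid"), inherits(frame, "isocenter_frame"))
  d_iso <- interp_at_point(dose, frame$isocenter)
  if (!is.finite(d_iso) || d_iso <= 0)
    .stopf("invalid input: isocenter dose must be > 0 (got %g)", d_iso)
  d <- dim(dose$values)
  width_along <- function(model_axis) {
    grid_axis <- abs(frame$axis_map[model_axis])
    others <- setdiff(1:3, grid_axis)
    slab <- integer(3)
    for (a in others) {
      fi <- (frame$isocenter[a] - dose$origin[a]) / dose$spacing[a] + 1
      slab[a] <- min(max(round(fi), 1L), d[a])
    }
    idx <- lapply(1:3, function(a) if (a == grid_axis) seq_len(d[a]) else slab[a])
    prof <- as.numeric(dose$values[idx[[1]], idx[[2]], idx[[3]]])
    above <- which(prof >= fraction * d_iso)
    if (length(above) == 0L) return(0)
    (max(above) - min(above) + 1L) * dose$spacing[grid_axis]
  }
  wy <- width_along(2L)  # left-right
  wz <- width_along(3L)  # craniocaudal
  list(width_y = wy, width_z = wz, F_U = wy * wz)
}
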