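# Voxel dose grids and the isocenter-origin model frame.
#
# A dose_grid is a uniform rectilinear voxel grid: `values` is a 3D array
# indexed [i, j, k] along the three grid axes, `spacing` the voxel size per
# axis (cm) and `origin` the physical position of the center of voxel
# (1,1,1) (cm).  Units of `values` are tracked as a string only.

#' Construct a voxel dose grid
#'
#' @param values 3D numeric array of per-voxel values.
#' @param spacing voxel size per grid axis, cm (length 3, positive).
#' @param origin physical position of the first voxel center, cm (length 3).
#' @param units unit label for `values` (`"mGy/MU"`, `"mGy"`, `"mGy/Gy"`,
#'   `"relative"`, or `"label"`).
#' @param rel_error optional per-voxel relative error (fraction), same
#'   dimensions as `values`.
#' @return An object of class `"dose_grid"`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0),
                      units = "mGy/MU", rel_error = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .stopf("invalid grid: 'values' must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .stopf("invalid grid: 'spacing' must be 3 positive numbers (cm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    .stopf("invalid grid: 'origin' must be 3 finite numbers (cm)")
  if (!is.null(rel_error)) {
    if (!identical(dim(rel_error), dim(values)))
      .stopf("invalid grid: 'rel_error' dimensions must match 'values'")
    if (any(rel_error < 0, na.rm = TRUE))
      .stopf("invalid grid: 'rel_error' must be non-negative")
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 units = units, rel_error = rel_error),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dose_grid: %d x %d x %d voxels, spacing (%g, %g, %g) cm, units %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$units))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  origin (%g, %g, %g) cm, value range [%.4g, %.4g]%s\n",
              x$origin[1], x$origin[2], x$origin[3], rng[1], rng[2],
              if (is.null(x$rel_error)) "" else ", rel_error attached"))
  invisible(x)
}

#' Physical voxel-center coordinates along one grid axis
#' @noRd
.axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

#' Isocenter-origin frame for a grid
#'
#' Maps grid indices to the model's patient coordinate frame: x
#' anterior-posterior, y left-right, z caudal-cranial, origin at the
#' treatment isocenter.  `axis_map` is a signed permutation of the grid
#' axes: entry `k` holds `+a` or `-a` meaning model axis `k` runs along
#' grid axis `a`, with the sign giving its direction.
#'
#' @param isocenter physical isocenter position in grid coordinates, cm.
#' @param axis_map signed permutation of `1:3`; default `c(1, 2, 3)`
#'   (grid axes already ordered AP, LR, craniocaudal).
#' @return An object of class `"isocenter_frame"`.
#' @examples
#' isocenter_frame(c(0, 0, 0))
#' isocenter_frame(c(25, 25, 40), axis_map = c(2, 1, -3))
#' @export
isocenter_frame <- function(isocenter, axis_map = c(1, 2, 3)) {
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || any(!is.finite(isocenter)))
    .stopf("invalid frame: 'isocenter' must be 3 finite numbers (cm)")
  axis_map <- as.integer(axis_map)
  if (length(axis_map) != 3L || !setequal(abs(axis_map), 1:3))
    .stopf("configuration error: 'axis_map' must be a signed permutation of 1:3")
  structure(list(isocenter = isocenter, axis_map = axis_map),
            class = "isocenter_frame")
}

#' Voxel-center coordinates in the model frame
#'
#' Translates voxel centers so the isocenter is the origin and permutes /
#' signs the axes per the frame's `axis_map`.
#'
#' @param grid a [dose_grid()] (only its geometry is used).
#' @param frame an [isocenter_frame()].
#' @return A list of three arrays `x`, `y`, `z` with the grid's
#'   dimensions, plus `r` (distance to the isocenter), all in cm.
#' @export
voxel_coords_in_model_frame <- function(grid, frame) {
  stopifnot(inherits(grid, "dose_grid"), inherits(frame, "isocenter_frame"))
  d <- dim(grid$values)
  # centered coordinate vector along each *grid* axis
  cent <- lapply(1:3, function(a) .axis_centers(grid, a) - frame$isocenter[a])
  model <- vector("list", 3L)
  for (k in 1:3) {
    a <- abs(frame$axis_map[k])
    s <- sign(frame$axis_map[k])
    v <- s * cent[[a]]
    # expand the per-axis vector to the full grid along grid axis a
    perm_dim <- c(d[a], d[-a])
    arr <- array(v, dim = perm_dim)
    model[[k]] <- aperm(arr, order(c(a, (1:3)[-a])))
  }
  names(model) <- c("x", "y", "z")
  model$r <- sqrt(model$x^2 + model$y^2 + model$z^2)
  model
}

#' Trilinear interpolation of a grid value at a physical point
#'
#' @param grid a [dose_grid()].
#' @param point physical position, cm (grid coordinates, length 3).
#' @return Interpolated scalar value.
#' @export
interp_at_point <- function(grid, point) {
  stopifnot(inherits(grid, "dose_grid"))
  point <- as.numeric(point)
  d <- dim(grid$values)
  # fractional index of the point on each axis
  fi <- (point - grid$origin) / grid$spacing + 1
  if (any(fi < 1 - 1e-9) || any(fi > d + 1e-9))
    .stopf("invalid input: point (%g, %g, %g) lies outside the grid",
           point[1], point[2], point[3])
  fi <- pmin(pmax(fi, 1), d)
  i0 <- pmin(floor(fi), pmax(d - 1, 1))
  w <- fi - i0
  i1 <- pmin(i0 + 1, d)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
    if (wt > 0)
      acc <- acc + wt * grid$values[ifelse(dx == 1, i1[1], i0[1]),
                                    ifelse(dy == 1, i1[2], i0[2]),
                                    ifelse(dz == 1, i1[3], i0[3])]
  }
  acc
}

#' Compute a whole-grid peripheral-dose cube
#'
#' Evaluates the model at every voxel center of a grid.  Voxels inside the
#' exclusion mask (in-field) or closer than `r_min` to the isocenter are
#' not computed: they carry `NA` and are flagged invalid in the companion
#' `valid` mask, so downstream statistics can skip them explicitly rather
#' than absorbing silent zeros.
#'
#' @param grid a [dose_grid()] supplying the geometry.
#' @param frame an [isocenter_frame()].
#' @param params [treatment_parameters()].
#' @param ref [reference_constants()].
#' @param coeffs [model_coefficients()].
#' @param exclusion_mask optional logical array (grid dims): `TRUE` voxels
#'   are skipped (typically the in-field 5\% isodose region).
#' @return A [dose_grid()] in mGy/MU with an extra element `valid`
#'   (logical array) marking computed voxels.
#' @export
compute_ppd_cube <- function(grid, frame, params,
                             ref = reference_constants(),
                             coeffs = model_coefficients(),
                             exclusion_mask = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(frame, "isocenter_frame"))
  d <- dim(grid$values)
  if (!is.null(exclusion_mask) && !identical(dim(exclusion_mask), d))
    .stopf("invalid input: exclusion_mask dimensions must match the grid")
  co <- voxel_coords_in_model_frame(grid, frame)
  valid <- co$r >= ref$r_min
  if (!is.null(exclusion_mask)) valid <- valid & !exclusion_mask
  vals <- array(NA_real_, dim = d)
  if (any(valid))
    vals[valid] <- ppd_at_point(co$x[valid], co$y[valid], co$z[valid],
                                params, ref, coeffs)
  out <- dose_grid(vals, grid$spacing, grid$origin, units = "mGy/MU")
  out$valid <- valid
  out
}

#' In-field mask from a planning-system dose distribution
#'
#' Marks voxels whose dose is at least `fraction` of the dose at the
#' isocenter (trilinearly interpolated).  The model applies only outside
#' this region, where planning systems stop being accurate.
#'
#' @param tps_dose a [dose_grid()] covering the isocenter.
#' @param frame an [isocenter_frame()].
#' @param fraction isodose threshold fraction (default 0.05).
#' @return Logical array over the grid: `TRUE` inside the field.
#' @export
in_field_mask <- function(tps_dose, frame, fraction = 0.05) {
  stopifnot(inherits(tps_dose, "dose_grid"), inherits(frame, "isocenter_frame"))
  d_iso <- interp_at_point(tps_dose, frame$isocenter)
  if (!is.finite(d_iso) || d_iso <= 0)
    .stopf("invalid input: dose interpolated at the isocenter is %g; it must be > 0",
           d_iso)
  tps_dose$values >= fraction * d_iso
}

#' Interior of a body mask
#'
#' Erodes a boolean body mask by one voxel with 6-connectivity, removing
#' the one-voxel surface shell where electron contamination makes the
#' model unreliable.
#'
#' @param body_mask logical 3D array.
#' @return Logical array of the same dimensions: the eroded interior.
#' @export
body_interior_mask <- function(body_mask) {
  if (!is.array(body_mask) || length(dim(body_mask)) != 3L)
    .stopf("invalid input: body_mask must be a logical 3D array")
  m <- body_mask & TRUE  # coerce to logical
  d <- dim(m)
  shift <- function(arr, axis, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (abs(by) >= n) return(out)
    if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
    else if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- m
  for (axis in 1:3) for (by in c(-1L, 1L))
    out <- out & shift(m, axis, by)
  out
}
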