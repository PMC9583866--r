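# Synthetic voxel phantoms, reference dose cubes and pseudo point-dosimeter
# sets.  These stand in for the reference computational and physical
# anthropomorphic phantoms so that every pipeline stage -- field-size
# extraction, calibration, cube computation, DVHs, point comparison -- is
# testable end to end.  They are deliberately simple (ellipsoids, uniform
# grids): no anatomical realism and no electron-density heterogeneity,
# which the analytical model ignores anyway.

#' Specification of a synthetic voxel phantom
#'
#' A body-shaped ellipsoid plus a few named ellipsoidal organs on a
#' uniform grid.  Default dimensions emulate an adult trunk: body
#' semi-axes 12 (anterior-posterior) x 17 (left-right) x 40 (craniocaudal)
#' cm on a 2 cm isotropic grid, isocenter at mid-abdomen (the body
#' center).
#'
#' @param body_semiaxes body ellipsoid semi-axes (AP, LR, CC), cm.
#' @param organs named list of organs, each a list with `center` (cm,
#'   isocenter-origin model frame) and `semiaxes` (cm).
#' @param dims grid voxel counts.
#' @param spacing voxel size, cm (length 3).
#' @param isocenter isocenter position in grid physical coordinates, cm.
#' @param origin position of the first voxel center, cm.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(body_semiaxes = c(12, 17, 40),
                         organs = list(
                           liver   = list(center = c(2, 5, 8),
                                          semiaxes = c(6, 8, 6)),
                           bladder = list(center = c(0, 0, -24),
                                          semiaxes = c(4, 4, 4)),
                           thyroid = list(center = c(3, 0, 34),
                                          semiaxes = c(2, 3, 2))),
                         dims = c(17, 21, 45),
                         spacing = c(2, 2, 2),
                         isocenter = c(0, 0, 0),
                         origin = NULL) {
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  spec <- structure(list(body_semiaxes = body_semiaxes, organs = organs,
                         dims = as.integer(dims), spacing = spacing,
                         isocenter = isocenter, origin = origin),
                    class = "phantom_spec")
  for (nm in names(organs)) {
    o <- organs[[nm]]
    # cheap per-axis necessary condition; generate_phantom() does the
    # exact voxelized containment check
    reach <- abs(o$center) + o$semiaxes
    if (any(reach > body_semiaxes))
      .stopf("spec error: organ '%s' extends outside the body ellipsoid", nm)
  }
  spec
}

.ellipsoid_mask <- function(co, center, semiaxes) {
  ((co$x - center[1]) / semiaxes[1])^2 +
    ((co$y - center[2]) / semiaxes[2])^2 +
    ((co$z - center[3]) / semiaxes[3])^2 <= 1
}

#' Voxelize a synthetic phantom
#'
#' Deterministic voxelization of the body and organ ellipsoids: a voxel
#' belongs to a mask when its center lies inside the ellipsoid.  Organ
#' labels are assigned in list order; overlapping organs raise an error.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `body` (logical array), `labels` (a label
#'   [dose_grid()], 0 = background), `names` (label name table), `grid`
#'   (an empty [dose_grid()] carrying the geometry), `frame` (the
#'   [isocenter_frame()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- dose_grid(array(0, dim = spec$dims), spec$spacing, spec$origin,
                    units = "relative")
  frame <- isocenter_frame(spec$isocenter)
  co <- voxel_coords_in_model_frame(geom, frame)
  body <- .ellipsoid_mask(co, c(0, 0, 0), spec$body_semiaxes)
  labels <- array(0L, dim = spec$dims)
  nm <- character(0)
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    m <- .ellipsoid_mask(co, o$center, o$semiaxes)
    if (any(m & !body))
      .stopf("spec error: organ '%s' has voxels outside the body",
             names(spec$organs)[i])
    if (any(labels[m] != 0L))
      .stopf("spec error: organ '%s' overlaps another organ",
             names(spec$organs)[i])
    labels[m] <- i
    nm[as.character(i)] <- names(spec$organs)[i]
  }
  lab_grid <- dose_grid(labels, spec$spacing, spec$origin, units = "label")
  list(body = body, labels = lab_grid, names = nm, grid = geom, frame = frame)
}

#' Generate a synthetic reference peripheral-dose cube
#'
#' Emulates a Monte Carlo reference dose distribution: the analytical
#' model evaluated at every voxel center, multiplied by voxel-wise
#' `(1 + noise_cv * N(0,1))` noise (relative noise, mirroring how MC
#' uncertainty is reported as a relative-error array), plus an optional
#' in-field Gaussian high-dose blob at the isocenter so a 5\% isodose
#' region exists.  Voxels inside `r_min` take the blob dose only.
#'
#' @param phantom result of [generate_phantom()].
#' @param coeffs [model_coefficients()] generating the cube.
#' @param params [treatment_parameters()]; default is a reference-style
#'   plan (epsilon = F = 1, `L_u = L_r`).
#' @param ref [reference_constants()].
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 for a noiseless cube).
#' @param blob `NULL`, or a list with `amplitude` (same units as the
#'   cube) and `sigma` (cm) for the in-field Gaussian.
#' @param seed integer seed for the noise.
#' @return A [dose_grid()] in mGy/MU with `rel_error` set to `noise_cv`.
#' @export
generate_reference_dose <- function(phantom,
                                    coeffs = model_coefficients(),
                                    params = NULL,
                                    ref = reference_constants(),
                                    noise_cv = 0.05,
                                    blob = list(amplitude = 7.2, sigma = 2),
                                    seed = 1L) {
  if (noise_cv < 0) .stopf("spec error: noise_cv must be >= 0")
  if (is.null(params))
    params <- treatment_parameters(prescription = 2000, total_MU = 278,
                                   F_U = ref$F_R, L_u = ref$L_r)
  geom <- phantom$grid
  co <- voxel_coords_in_model_frame(geom, phantom$frame)
  d <- dim(geom$values)
  vals <- array(0, dim = d)
  outside <- co$r >= ref$r_min
  vals[outside] <- ppd_at_point(co$x[outside], co$y[outside], co$z[outside],
                                params, ref, coeffs)
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    vals <- vals * (1 + noise_cv * stats::rnorm(length(vals)))
    vals[vals < 0] <- 0
  }
  if (!is.null(blob))
    vals <- vals + blob$amplitude * exp(-co$r^2 / (2 * blob$sigma^2))
  dose_grid(vals, geom$spacing, geom$origin, units = "mGy/MU",
            rel_error = array(noise_cv, dim = d))
}

#' Generate pseudo point-dosimeter measurements
#'
#' Scattered points, uniform over an annulus between `r_range[1]` and
#' `r_range[2]` cm from the isocenter (emulating dosimeter chips spread
#' through internal organs), with the model value as truth and
#' multiplicative Gaussian noise as the "measurement".
#'
#' @param n number of points.
#' @param r_range inner and outer radius, cm; the inner radius must clear
#'   the in-field region.
#' @param coeffs [model_coefficients()].
#' @param params [treatment_parameters()].
#' @param ref [reference_constants()].
#' @param noise_cv measurement coefficient of variation.
#' @param seed integer seed.
#' @return A data frame with columns `x`, `y`, `z`, `r`, `true_value`,
#'   `measured`.
#' @export
generate_tld_points <- function(n, r_range = c(8, 45),
                                coeffs = model_coefficients(),
                                params = NULL,
                                ref = reference_constants(),
                                noise_cv = 0.05, seed = 1L) {
  if (n < 1) .stopf("spec error: n must be >= 1")
  if (r_range[1] >= r_range[2] || r_range[1] < ref$r_min)
    .stopf("spec error: empty or invalid annulus [%g, %g]",
           r_range[1], r_range[2])
  if (is.null(params))
    params <- treatment_parameters(prescription = 2000, total_MU = 278,
                                   F_U = ref$F_R, L_u = ref$L_r)
  set.seed(as.integer(seed))
  # uniform in volume over the annulus, isotropic directions
  u <- stats::runif(n)
  r <- (r_range[1]^3 + u * (r_range[2]^3 - r_range[1]^3))^(1 / 3)
  zdir <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - zdir^2)
  x <- r * s * cos(phi); y <- r * s * sin(phi); z <- r * zdir
  true_value <- ppd_at_point(x, y, z, params, ref, coeffs)
  measured <- true_value * (1 + noise_cv * stats::rnorm(n))
  measured[measured <= 0] <- .Machine$double.eps
  data.frame(x = x, y = y, z = z, r = r,
             true_value = true_value, measured = measured)
}
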