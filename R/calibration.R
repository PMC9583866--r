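# Calibration of the three model coefficients against a reference 3D dose
# distribution, and agreement statistics between model and reference.

#' Voxel mask used for coefficient fitting
#'
#' The fit uses only voxels that are (i) in the interior of the body
#' (one-voxel surface shell eroded away, since electron contamination is
#' not modelled), (ii) outside the in-field isodose region, and (iii) at a
#' radius between `r_min` and `r_cut` from the isocenter (the reference
#' data extends no farther; beyond, only leakage is modelled).
#'
#' @param reference a [dose_grid()] with the reference dose (mGy/MU).
#' @param frame an [isocenter_frame()].
#' @param body_mask logical array (grid dims): the body voxels.
#' @param ref [reference_constants()].
#' @param tps_dose optional [dose_grid()] used for the in-field isodose
#'   threshold; defaults to `reference` itself.
#' @return Logical array: voxels eligible for fitting.
#' @export
calibration_mask <- function(reference, frame, body_mask,
                             ref = reference_constants(),
                             tps_dose = reference) {
  stopifnot(inherits(reference, "dose_grid"), inherits(frame, "isocenter_frame"))
  d <- dim(reference$values)
  if (!identical(dim(body_mask), d))
    .stopf("invalid input: body_mask dimensions must match the reference grid")
  co <- voxel_coords_in_model_frame(reference, frame)
  mask <- body_interior_mask(body_mask) &
    !in_field_mask(tps_dose, frame, ref$isodose_exclusion) &
    co$r <= ref$r_cut & co$r >= ref$r_min
  if (!any(mask))
    .stopf("fit infeasible: the calibration mask is empty")
  mask
}

#' Fit the model coefficients to a reference dose distribution
#'
#' Minimizes, by Nelder-Mead simplex, the sum over masked voxels of
#' squared relative residuals `((model - ref)/ref)^2` (default) or squared
#' absolute residuals.  Relative residuals are the default because
#' peripheral dose spans roughly two orders of magnitude over the body and
#' absolute least squares would be dominated by near-field voxels.  The
#' fit evaluates the model with `epsilon = F = 1` and `L_u = L_r`
#' (reference-treatment conditions).  Deterministic for a fixed start.
#'
#' @param reference a [dose_grid()] with reference dose per MU.
#' @param mask logical array of voxels to fit on (e.g. from
#'   [calibration_mask()]).
#' @param frame an [isocenter_frame()].
#' @param ref [reference_constants()].
#' @param start numeric length-3 starting point `(A1, A2, A3)`.
#' @param loss `"relative"` (default) or `"absolute"` squared residuals.
#' @param weights optional per-voxel weights (grid dims); e.g.
#'   `1/sigma^2` from a `.3ddose` relative-error array.  Uniform by
#'   default.
#' @param maxit maximum simplex iterations.
#' @param reltol relative convergence tolerance on the objective.
#' @return An object of class `"fit_result"`: `coefficients`
#'   ([model_coefficients()]), `objective_value`, `n_voxels`, `converged`,
#'   `start`, `loss`.
#' @export
fit_coefficients <- function(reference, mask, frame,
                             ref = reference_constants(),
                             start = c(20, 0.3, 0.02),
                             loss = c("relative", "absolute"),
                             weights = NULL,
                             maxit = 5000, reltol = 1e-8) {
  stopifnot(inherits(reference, "dose_grid"), inherits(frame, "isocenter_frame"))
  loss <- match.arg(loss)
  if (!identical(dim(mask), dim(reference$values)))
    .stopf("invalid input: mask dimensions must match the reference grid")
  if (!any(mask)) .stopf("fit infeasible: empty mask")
  y <- reference$values[mask]
  if (any(!is.finite(y)) || any(y <= 0))
    .stopf("invalid input: reference values on the mask must be finite and > 0")
  co <- voxel_coords_in_model_frame(reference, frame)
  r <- co$r[mask]
  absz <- abs(co$z[mask])
  w <- if (is.null(weights)) rep(1, length(y)) else {
    if (!identical(dim(weights), dim(reference$values)))
      .stopf("invalid input: weights dimensions must match the reference grid")
    weights[mask]
  }
  # model under reference conditions (eps = F = 1, L_u = L_r)
  predict_ppd <- function(p) {
    pmax((p[1] - p[2] * absz) * exp(-p[3] * r) / r^2, 0)
  }
  objective <- function(p) {
    if (p[1] <= 0 || p[2] < 0 || p[3] < 0) return(Inf)
    m <- predict_ppd(p)
    res <- if (loss == "relative") (m - y) / y else m - y
    sum(w * res^2)
  }
  ctrl <- list(maxit = maxit, reltol = reltol, parscale = pmax(abs(start), 1e-6))
  opt <- stats::optim(start, objective, method = "Nelder-Mead", control = ctrl)
  # one restart from the optimum guards against premature simplex collapse
  ctrl2 <- ctrl
  ctrl2$parscale <- pmax(abs(opt$par), 1e-6)
  opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead", control = ctrl2)
  if (opt2$value <= opt$value) opt <- opt2
  structure(list(
    coefficients = model_coefficients(opt$par[1], opt$par[2], opt$par[3]),
    objective_value = opt$value,
    n_voxels = length(y),
    converged = opt$convergence == 0L,
    start = start,
    loss = loss), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Coefficient fit on %d voxels (%s loss), %s:\n", x$n_voxels,
              x$loss, if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients)
  cat(sprintf("  objective = %.6g\n", x$objective_value))
  invisible(x)
}

.agreement_from_pairs <- function(model, reference, per_point = NULL) {
  if (any(reference <= 0))
    .stopf("invalid input: reference values must be > 0")
  abs_diff <- abs(model - reference)
  pct <- 100 * abs_diff / reference
  structure(list(
    p95_abs_pct_diff = unname(stats::quantile(pct, 0.95)),
    mean_abs_pct_diff = mean(pct),
    max_abs_diff = max(abs_diff),
    n = length(model),
    per_point = per_point), class = "agreement_stats")
}

#' Agreement statistics between a model cube and a reference cube
#'
#' Per-voxel absolute percentage differences relative to the reference:
#' reports their 95th percentile and mean, and the maximum absolute
#' difference in dose units.
#'
#' @param model_cube,reference [dose_grid()] objects of equal dimensions.
#' @param mask logical array of voxels to compare.
#' @return An object of class `"agreement_stats"` with
#'   `p95_abs_pct_diff`, `mean_abs_pct_diff` (both %), `max_abs_diff`
#'   (dose units) and `n`.
#' @export
agreement_stats <- function(model_cube, reference, mask = NULL) {
  stopifnot(inherits(model_cube, "dose_grid"), inherits(reference, "dose_grid"))
  d <- dim(reference$values)
  if (!identical(dim(model_cube$values), d))
    .stopf("invalid input: cube dimensions differ")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!identical(dim(mask), d))
    .stopf("invalid input: mask dimensions must match the cubes")
  m <- model_cube$values[mask]
  y <- reference$values[mask]
  keep <- is.finite(m) & is.finite(y)
  if (!any(keep)) .stopf("invalid input: no finite voxel pairs to compare")
  .agreement_from_pairs(m[keep], y[keep])
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement over %d points:\n", x$n))
  cat(sprintf("  95%% of |diff|/ref below %.3g%%, mean %.3g%%, max |diff| %.4g\n",
              x$p95_abs_pct_diff, x$mean_abs_pct_diff, x$max_abs_diff))
  invisible(x)
}

#' Compare predicted and measured point doses
#'
#' Pairs model predictions with point measurements (e.g. thermoluminescent
#' dosimeter readings) and computes the same agreement statistics as
#' [agreement_stats()], plus a per-point table.
#'
#' @param predicted data frame with columns `x`, `y`, `z` (cm) and
#'   `value`, or a numeric vector of predicted values.
#' @param measured same layout as `predicted`; values must be positive.
#' @return An `"agreement_stats"` object whose `per_point` element is a
#'   data frame with the paired values, absolute and percentage
#'   differences.
#' @export
compare_point_doses <- function(predicted, measured) {
  get_vals <- function(obj, what) {
    if (is.data.frame(obj)) {
      if (!"value" %in% names(obj))
        .stopf("invalid input: %s data frame needs a 'value' column", what)
      obj$value
    } else as.numeric(obj)
  }
  p <- get_vals(predicted, "predicted")
  m <- get_vals(measured, "measured")
  if (length(p) != length(m))
    .stopf("invalid input: predicted (%d) and measured (%d) lengths differ",
           length(p), length(m))
  if (length(p) == 0L) .stopf("invalid input: empty point lists")
  tab <- data.frame(predicted = p, measured = m,
                    abs_diff = abs(p - m),
                    abs_pct_diff = 100 * abs(p - m) / m)
  if (is.data.frame(predicted) && all(c("x", "y", "z") %in% names(predicted)))
    tab <- cbind(predicted[c("x", "y", "z")], tab)
  .agreement_from_pairs(p, m, per_point = tab)
}
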