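#' @keywords internal
"_PACKAGE"

# Default calibrated coefficients and reference-treatment constants.
# Reference plan: eight equally spaced coplanar 6 MV beams, 10 x 10 cm2
# open fields, isocenter at mid-abdomen, 2 Gy in 278 MU.
.peridose_defaults <- list(
  A1 = 37.890,           # mGy cm^2 / MU
  A2 = 0.679,            # mGy cm / MU
  A3 = 0.007,            # cm^-1
  E_R = 2000 / 278,      # mGy/MU, printed as 7.2
  F_R = 149.2,           # cm^2
  L_r = 0.001,           # mGy/MU
  r_cut = 40,            # cm; leakage-only radius
  r_min = 1,             # cm; validity guard near the isocenter
  isodose_exclusion = 0.05
)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("invalid parameter: '%s' must be a finite numeric scalar", name)
  if (positive && x <= 0)
    .stopf("invalid parameter: '%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0)
    .stopf("invalid parameter: '%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

#' Model coefficients of the peripheral-dose equation
#'
#' The analytical model carries three fitted constants: `A1` (mGy cm^2/MU),
#' the amplitude of the scatter term; `A2` (mGy cm/MU), the craniocaudal
#' gradient; and `A3` (cm^-1), an effective attenuation coefficient of the
#' scattered photons.  Defaults are the coefficients calibrated against a
#' Monte Carlo reference abdomen treatment.
#'
#' @param A1 scatter amplitude, mGy cm^2/MU; must be positive.
#' @param A2 craniocaudal gradient, mGy cm/MU; must be non-negative.
#' @param A3 effective attenuation, cm^-1; must be non-negative.
#' @return An object of class `"model_coefficients"`.
#' @examples
#' model_coefficients()
#' model_coefficients(A1 = 40, A2 = 0.7, A3 = 0.008)
#' @export
model_coefficients <- function(A1 = .peridose_defaults$A1,
                               A2 = .peridose_defaults$A2,
                               A3 = .peridose_defaults$A3) {
  .check_scalar(A1, "A1")
  .check_scalar(A2, "A2", positive = FALSE, nonneg = TRUE)
  .check_scalar(A3, "A3", positive = FALSE, nonneg = TRUE)
  if (A1 - A2 * .peridose_defaults$r_cut <= 0)
    .stopf(paste0("invalid parameter: A1 - A2*%g must stay positive so the ",
                  "scatter bracket is positive everywhere it applies"),
           .peridose_defaults$r_cut)
  structure(list(A1 = A1, A2 = A2, A3 = A3), class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("Peripheral-dose model coefficients:\n")
  cat(sprintf("  A1 = %.6g mGy cm^2/MU\n  A2 = %.6g mGy cm/MU\n  A3 = %.6g cm^-1\n",
              x$A1, x$A2, x$A3))
  invisible(x)
}

#' Treatment-specific parameters
#'
#' Everything the model needs to know about the user's plan: the treatment
#' efficiency `E_U` (prescribed isocenter dose per monitor unit), the field
#' area `F_U` from the 50% isodose, the measured head leakage `L_u` (falls
#' back to the reference leakage when unknown), the total monitor units and
#' the prescription.  `E_U` is derived from `prescription`/`total_MU` when
#' not given directly.
#'
#' @param prescription isocenter dose for the whole treatment, mGy.
#' @param total_MU total monitor units delivered.
#' @param F_U field area from the 50% isodose, cm^2.
#' @param L_u linac head leakage, mGy/MU; defaults to the reference value
#'   so the leakage-difference term vanishes.
#' @param E_U treatment efficiency, mGy/MU; computed from the prescription
#'   and MU when `NULL`.
#' @return An object of class `"treatment_parameters"`.
#' @examples
#' treatment_parameters(prescription = 1800, total_MU = 498, F_U = 53.2,
#'                      L_u = 0.0032)
#' @export
treatment_parameters <- function(prescription, total_MU, F_U,
                                 L_u = .peridose_defaults$L_r,
                                 E_U = NULL) {
  .check_scalar(prescription, "prescription")
  .check_scalar(total_MU, "total_MU")
  if (total_MU < 1) .stopf("invalid parameter: total_MU must be >= 1")
  .check_scalar(F_U, "F_U")
  .check_scalar(L_u, "L_u", positive = FALSE, nonneg = TRUE)
  if (is.null(E_U)) E_U <- treatment_efficiency(prescription, total_MU)
  .check_scalar(E_U, "E_U")
  structure(list(E_U = E_U, F_U = F_U, L_u = L_u,
                 total_MU = total_MU, prescription = prescription),
            class = "treatment_parameters")
}

#' @export
print.treatment_parameters <- function(x, ...) {
  cat("Treatment parameters:\n")
  cat(sprintf("  prescription = %g mGy in %g MU (E_U = %.4g mGy/MU)\n",
              x$prescription, x$total_MU, x$E_U))
  cat(sprintf("  F_U = %g cm^2, L_u = %g mGy/MU\n", x$F_U, x$L_u))
  invisible(x)
}

#' Reference-treatment constants
#'
#' Constants fixed by the calibration conditions: reference efficiency
#' `E_R`, reference field area `F_R`, reference leakage `L_r`, the radius
#' `r_cut` beyond which only leakage contributes, the validity guard
#' `r_min` near the isocenter and the in-field isodose exclusion fraction.
#'
#' @param E_R reference efficiency, mGy/MU.
#' @param F_R reference field area, cm^2.
#' @param L_r reference leakage, mGy/MU.
#' @param r_cut leakage-only radius, cm.
#' @param r_min validity guard radius, cm.
#' @param isodose_exclusion in-field exclusion fraction, in (0, 1).
#' @return An object of class `"reference_constants"`.
#' @export
reference_constants <- function(E_R = .peridose_defaults$E_R,
                                F_R = .peridose_defaults$F_R,
                                L_r = .peridose_defaults$L_r,
                                r_cut = .peridose_defaults$r_cut,
                                r_min = .peridose_defaults$r_min,
                                isodose_exclusion = .peridose_defaults$isodose_exclusion) {
  .check_scalar(E_R, "E_R"); .check_scalar(F_R, "F_R")
  .check_scalar(L_r, "L_r"); .check_scalar(r_cut, "r_cut")
  .check_scalar(r_min, "r_min")
  .check_scalar(isodose_exclusion, "isodose_exclusion")
  if (isodose_exclusion >= 1)
    .stopf("invalid parameter: isodose_exclusion must be in (0, 1)")
  structure(list(E_R = E_R, F_R = F_R, L_r = L_r, r_cut = r_cut,
                 r_min = r_min, isodose_exclusion = isodose_exclusion),
            class = "reference_constants")
}

#' Treatment efficiency
#'
#' Prescribed isocenter dose per monitor unit, `E = D_iso / MU` in mGy/MU.
#' Carried at full precision; printed values such as 7.2 are display
#' roundings.
#'
#' @param prescription isocenter dose, mGy.
#' @param total_MU monitor units delivering it.
#' @return Efficiency in mGy/MU.
#' @examples
#' treatment_efficiency(2000, 278)  # 7.194..., printed as 7.2
#' @export
treatment_efficiency <- function(prescription, total_MU) {
  .check_scalar(prescription, "prescription")
  .check_scalar(total_MU, "total_MU")
  prescription / total_MU
}

#' Efficiency correction factor
#'
#' Ratio of the user's treatment efficiency to the reference efficiency,
#' `epsilon = E_U / E_R`.  It rescales the scatter term for plans that
#' deliver their prescription with a different number of monitor units
#' than the reference plan.
#'
#' @param E_U user efficiency, mGy/MU.
#' @param E_R reference efficiency, mGy/MU.
#' @return Dimensionless correction factor.
#' @examples
#' efficiency_factor(3.6, 7.2)  # 0.5
#' @export
efficiency_factor <- function(E_U, E_R = .peridose_defaults$E_R) {
  .check_scalar(E_U, "E_U")
  .check_scalar(E_R, "E_R")
  E_U / E_R
}

#' Field-size correction factor
#'
#' Ratio of the user field area to the reference field area,
#' `F = F_U / F_R`, both taken as the average of the areas inside the 50%
#' isodose on the coronal and sagittal planes through the isocenter.
#'
#' @param F_U user field area, cm^2.
#' @param F_R reference field area, cm^2.
#' @return Dimensionless correction factor.
#' @examples
#' field_factor(53.2)  # 0.357, printed as 0.35
#' @export
field_factor <- function(F_U, F_R = .peridose_defaults$F_R) {
  .check_scalar(F_U, "F_U")
  .check_scalar(F_R, "F_R")
  F_U / F_R
}

#' Peripheral photon dose per monitor unit at a point
#'
#' Evaluates the piecewise peripheral-dose equation in the isocenter-origin
#' frame (x anterior-posterior, y left-right, z caudal-cranial, all cm).
#' For radii `r <= r_cut` the dose per MU is
#' `eps * F * (A1 - A2*|z|) * exp(-A3*r) / r^2 + (L_u - L_r)`,
#' clamped below at zero; beyond `r_cut` only head leakage remains and the
#' value is exactly `L_u`.  The model is valid only outside the in-field
#' (5\% isodose) region; the caller is responsible for masking in-field
#' points, and radii below `r_min` raise an out-of-validity error.
#'
#' Inputs are vectorized over `x`, `y`, `z`.
#'
#' @param x,y,z point coordinates in the isocenter frame, cm.
#' @param params [treatment_parameters()] for the user's plan.
#' @param ref [reference_constants()].
#' @param coeffs [model_coefficients()].
#' @return Dose per monitor unit, mGy/MU (vector matching the inputs).
#' @examples
#' p <- treatment_parameters(2000, 278, F_U = 149.2)
#' ppd_at_point(0, 0, 10, p)   # 0.290 mGy/MU
#' ppd_at_point(0, 0, 50, p)   # leakage plateau: L_u
#' @export
ppd_at_point <- function(x, y, z, params,
                         ref = reference_constants(),
                         coeffs = model_coefficients()) {
  stopifnot(inherits(params, "treatment_parameters"),
            inherits(ref, "reference_constants"),
            inherits(coeffs, "model_coefficients"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r < ref$r_min))
    .stopf(paste0("out of validity: %d point(s) closer than r_min = %g cm ",
                  "to the isocenter; the model is undefined inside the ",
                  "in-field region"), sum(r < ref$r_min), ref$r_min)
  eps <- efficiency_factor(params$E_U, ref$E_R)
  f <- field_factor(params$F_U, ref$F_R)
  out <- rep(params$L_u, n)
  near <- r <= ref$r_cut
  if (any(near)) {
    scatter <- eps * f * (coeffs$A1 - coeffs$A2 * abs(z[near])) *
      exp(-coeffs$A3 * r[near]) / r[near]^2
    out[near] <- pmax(scatter + (params$L_u - ref$L_r), 0)
  }
  out
}

#' Absolute dose for the whole treatment
#'
#' @param ppd_per_MU dose per monitor unit, mGy/MU.
#' @param total_MU total monitor units of the treatment.
#' @return Absolute dose, mGy.
#' @export
absolute_dose <- function(ppd_per_MU, total_MU) {
  .check_scalar(total_MU, "total_MU")
  if (any(ppd_per_MU < 0, na.rm = TRUE))
    .stopf("invalid parameter: ppd_per_MU must be non-negative")
  ppd_per_MU * total_MU
}

#' Peripheral dose normalized to the isocenter dose
#'
#' Converts a per-MU peripheral dose to mGy per Gy delivered at the
#' isocenter, the axis convention used when plotting peripheral dose
#' against distance.
#'
#' @param ppd_per_MU dose per monitor unit, mGy/MU.
#' @param total_MU total monitor units.
#' @param prescription isocenter dose, mGy.
#' @return Dose in mGy per isocenter Gy.
#' @export
normalize_to_isocenter_dose <- function(ppd_per_MU, total_MU, prescription) {
  .check_scalar(total_MU, "total_MU")
  .check_scalar(prescription, "prescription")
  ppd_per_MU * total_MU / (prescription / 1000)
}

#' Read or write a plain-text model configuration
#'
#' Coefficients and reference constants round-trip through a `key=value`
#' text file.  Unknown keys raise an error; missing keys fall back to the
#' packaged defaults.
#'
#' @param path file to read or write.
#' @param coeffs,ref objects to serialize (for [write_model_config()]).
#' @return For [read_model_config()], a list with elements `coeffs` and
#'   `ref`; for [write_model_config()], the path, invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) .stopf("malformed config line: '%s'", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) .stopf("non-numeric config value for key '%s'",
                          keys[is.na(vals)][1])
  known <- c("A1", "A2", "A3", "E_R", "F_R", "L_r", "r_cut", "r_min",
             "isodose_exclusion")
  if (any(!keys %in% known))
    .stopf("unknown config key '%s'", setdiff(keys, known)[1])
  if (anyDuplicated(keys)) .stopf("duplicated config key '%s'",
                                  keys[duplicated(keys)][1])
  get <- function(k) if (k %in% keys) vals[keys == k] else .peridose_defaults[[k]]
  list(coeffs = model_coefficients(get("A1"), get("A2"), get("A3")),
       ref = reference_constants(get("E_R"), get("F_R"), get("L_r"),
                                 get("r_cut"), get("r_min"),
                                 get("isodose_exclusion")))
}

#' @rdname read_model_config
#' @export
write_model_config <- function(path, coeffs = model_coefficients(),
                               ref = reference_constants()) {
  stopifnot(inherits(coeffs, "model_coefficients"),
            inherits(ref, "reference_constants"))
  lines <- c(
    "# peripheral-dose model configuration",
    sprintf("A1=%.15g", coeffs$A1),
    sprintf("A2=%.15g", coeffs$A2),
    sprintf("A3=%.15g", coeffs$A3),
    sprintf("E_R=%.15g", ref$E_R),
    sprintf("F_R=%.15g", ref$F_R),
    sprintf("L_r=%.15g", ref$L_r),
    sprintf("r_cut=%.15g", ref$r_cut),
    sprintf("r_min=%.15g", ref$r_min),
    sprintf("isodose_exclusion=%.15g", ref$isodose_exclusion))
  writeLines(lines, path)
  invisible(path)
}
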