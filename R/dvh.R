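# Organ dose-volume histograms from a peripheral-dose cube.

#' Cumulative dose-volume histogram for one organ
#'
#' `V(d)` is the percentage of the organ's voxels receiving at least dose
#' `d`, evaluated at the left edge of each bin.  Bins are uniform, from 0
#' to one bin past the organ maximum.  Voxels the model did not compute
#' (in-field sentinel `NA`) are excluded from the histogram and their
#' fraction reported; the planning system covers that region.
#'
#' @param dose a [dose_grid()] (any dose units); `NA` voxels are treated
#'   as not computed.
#' @param organ logical 3D array (grid dims) selecting the organ, or a
#'   list with elements `name` and `mask`.
#' @param bin_width histogram bin width in the dose units of `dose`
#'   (default 0.1, suited to small peripheral doses in mGy).
#' @param name organ label used in reports and exports.
#' @return An object of class `"dvh_curve"`: `bin_edges`,
#'   `cumulative_volume` (%), `d_min`, `d_max`, `d_mean`, `n_voxels`,
#'   `volume_cm3`, `excluded_fraction`, `name`, `bin_width`.
#' @export
cumulative_dvh <- function(dose, organ, bin_width = 0.1, name = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (is.list(organ) && !is.null(organ$mask)) {
    if (is.null(name)) name <- organ$name
    organ <- organ$mask
  }
  if (is.null(name)) name <- "organ"
  if (!identical(dim(organ), dim(dose$values)))
    .stopf("invalid input: organ mask dimensions must match the dose grid")
  .check_scalar(bin_width, "bin_width")
  n_total <- sum(organ)
  if (n_total == 0L) .stopf("invalid input: empty organ mask")
  v <- dose$values[organ]
  excl <- !is.finite(v)
  excluded_fraction <- mean(excl)
  if (excluded_fraction > 0.10)
    warning(sprintf("%.1f%% of '%s' voxels are inside the not-computed region",
                    100 * excluded_fraction, name), call. = FALSE)
  v <- v[!excl]
  if (length(v) == 0L)
    .stopf("invalid input: no computed dose voxels inside organ '%s'", name)
  d_max <- max(v)
  edges <- seq(0, d_max + bin_width, by = bin_width)
  cum_vol <- vapply(edges, function(d) 100 * mean(v >= d), numeric(1))
  structure(list(
    bin_edges = edges, cumulative_volume = cum_vol,
    d_min = min(v), d_max = d_max, d_mean = mean(v),
    n_voxels = length(v),
    volume_cm3 = length(v) * prod(dose$spacing),
    excluded_fraction = excluded_fraction,
    name = name, bin_width = bin_width), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("DVH '%s': %d voxels (%.1f cm^3), bin width %g\n",
              x$name, x$n_voxels, x$volume_cm3, x$bin_width))
  cat(sprintf("  Dmin %.4g, Dmean %.4g, Dmax %.4g%s\n", x$d_min, x$d_mean,
              x$d_max,
              if (x$excluded_fraction > 0)
                sprintf("  (%.1f%% of voxels not computed)",
                        100 * x$excluded_fraction) else ""))
  invisible(x)
}

#' Minimum, maximum and mean organ dose
#'
#' Plain statistics over the computed voxels of an organ mask (uniform
#' voxel volume, so the mean is volume-weighted by construction).
#'
#' @inheritParams cumulative_dvh
#' @return Named numeric vector `c(d_min, d_max, d_mean)`.
#' @export
dose_stats <- function(dose, organ) {
  stopifnot(inherits(dose, "dose_grid"))
  if (is.list(organ) && !is.null(organ$mask)) organ <- organ$mask
  if (!identical(dim(organ), dim(dose$values)))
    .stopf("invalid input: organ mask dimensions must match the dose grid")
  if (sum(organ) == 0L) .stopf("invalid input: empty organ mask")
  v <- dose$values[organ]
  v <- v[is.finite(v)]
  if (length(v) == 0L) .stopf("invalid input: no computed voxels in the organ")
  c(d_min = min(v), d_max = max(v), d_mean = mean(v))
}

#' Export a DVH curve as a plain-text ASCII table
#'
#' Two columns (dose, cumulative volume %), '#'-prefixed header lines
#' carrying the organ name, bin width and summary doses.  Decimal points
#' are locale-independent.
#'
#' @param curve a [cumulative_dvh()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_dvh_ascii <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  con <- try(suppressWarnings(file(path, open = "wt")), silent = TRUE)
  if (inherits(con, "try-error"))
    .stopf("I/O error: cannot open '%s' for writing", path)
  on.exit(close(con))
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(Sys.setlocale("LC_NUMERIC", old), add = TRUE)
  Sys.setlocale("LC_NUMERIC", "C")
  writeLines(c(
    sprintf("# cumulative DVH for organ: %s", curve$name),
    sprintf("# bin_width: %.6g", curve$bin_width),
    sprintf("# n_voxels: %d  volume_cm3: %.6g  excluded_fraction: %.6g",
            curve$n_voxels, curve$volume_cm3, curve$excluded_fraction),
    sprintf("# d_min: %.6g  d_mean: %.6g  d_max: %.6g",
            curve$d_min, curve$d_mean, curve$d_max),
    "# dose  volume_pct"), con)
  writeLines(sprintf("%.6g %.6g", curve$bin_edges, curve$cumulative_volume),
             con)
  invisible(path)
}

#' Read back an exported DVH ASCII table
#'
#' @param path file written by [export_dvh_ascii()].
#' @return A `"dvh_curve"` reconstructed from the file.
#' @export
read_dvh_ascii <- function(path) {
  if (!file.exists(path)) .stopf("I/O error: file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  dat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  grab <- function(key) {
    ln <- grep(paste0(key, ":"), hdr, value = TRUE, fixed = TRUE)[1]
    as.numeric(sub(paste0(".*", key, ":\\s*(\\S+).*"), "\\1", ln))
  }
  name <- sub(".*organ:\\s*", "", grep("organ:", hdr, value = TRUE)[1])
  m <- do.call(rbind, lapply(strsplit(dat, "\\s+"), as.numeric))
  structure(list(
    bin_edges = m[, 1], cumulative_volume = m[, 2],
    d_min = grab("d_min"), d_max = grab("d_max"), d_mean = grab("d_mean"),
    n_voxels = as.integer(grab("n_voxels")),
    volume_cm3 = grab("volume_cm3"),
    excluded_fraction = grab("excluded_fraction"),
    name = name, bin_width = grab("bin_width")), class = "dvh_curve")
}
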