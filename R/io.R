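# Readers and writers: BEAMnrc/DOSXYZnrc .3ddose, NIfTI volumes, organ
# label volumes with a JSON name table, and JSON plan summaries.
#
# Internal geometry is always cm; NIfTI pixel dimensions are mm on disk
# and converted on read/write.  The .3ddose layout is: nx ny nz; then the
# nx+1, ny+1, nz+1 voxel boundary coordinates per axis; then nx*ny*nz
# dose values in x-fastest order; then the same count of relative errors.

#' Read a BEAMnrc/DOSXYZnrc .3ddose file
#'
#' Voxel centers are taken as boundary midpoints.  Boundaries must be
#' monotone and uniform (a rectilinear grid with non-uniform spacing is
#' rejected).  Boundary units are cm by convention; pass `mm = TRUE` for
#' nonstandard exports in mm.
#'
#' @param path path to the .3ddose file.
#' @param units unit label to attach to the dose values.
#' @param mm interpret boundary coordinates as mm instead of cm.
#' @return A [dose_grid()] with the relative-error array attached.
#' @export
read_3ddose <- function(path, units = "mGy/MU", mm = FALSE) {
  if (!file.exists(path)) .stopf("format error: file not found: %s", path)
  tok <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tok) < 3L) .stopf("format error in %s: missing voxel counts", path)
  n <- as.integer(tok[1:3])
  if (any(n < 1L)) .stopf("format error in %s: voxel counts must be >= 1", path)
  nvox <- prod(n)
  need <- 3L + sum(n + 1L) + 2L * nvox
  if (length(tok) < need)
    .stopf("format error in %s: expected %d numbers, found %d (truncated file?)",
           path, need, length(tok))
  pos <- 3L
  take <- function(k) {
    out <- tok[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  scale <- if (mm) 0.1 else 1
  bounds <- lapply(1:3, function(a) take(n[a] + 1L) * scale)
  for (a in 1:3) {
    db <- diff(bounds[[a]])
    if (any(db <= 0))
      .stopf("format error in %s: non-monotone voxel boundaries on axis %d",
             path, a)
    if (max(db) - min(db) > 1e-6 * max(db))
      .stopf("format error in %s: non-uniform voxel boundaries on axis %d are not supported",
             path, a)
  }
  spacing <- vapply(bounds, function(b) mean(diff(b)), numeric(1))
  origin <- vapply(bounds, function(b) (b[1] + b[2]) / 2, numeric(1))
  dose <- array(take(nvox), dim = n)       # x-fastest matches column-major
  err <- array(take(nvox), dim = n)
  dose_grid(dose, spacing, origin, units = units, rel_error = err)
}

#' Write a dose grid as a .3ddose file
#'
#' @param grid a [dose_grid()].
#' @param path output path.
#' @param mm write boundary coordinates in mm instead of cm.
#' @return The path, invisibly.
#' @export
write_3ddose <- function(grid, path, mm = FALSE) {
  stopifnot(inherits(grid, "dose_grid"))
  n <- dim(grid$values)
  scale <- if (mm) 10 else 1
  bounds <- lapply(1:3, function(a) {
    (grid$origin[a] + (seq_len(n[a] + 1L) - 1.5) * grid$spacing[a]) * scale
  })
  err <- grid$rel_error
  if (is.null(err)) err <- array(0, dim = n)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.9g", x), collapse = " ")
  writeLines(paste(n, collapse = " "), con)
  for (a in 1:3) writeLines(fmt(bounds[[a]]), con)
  writeLines(fmt(as.numeric(grid$values)), con)
  writeLines(fmt(as.numeric(err)), con)
  invisible(path)
}

#' Read a volume file into a dose grid
#'
#' Dispatches on extension: `.3ddose` via [read_3ddose()], `.nii` /
#' `.nii.gz` via RNifti.  NIfTI pixel dimensions (mm) and origin are
#' converted to cm.  DICOM and MetaImage inputs are not supported and
#' raise a format error naming the path.
#'
#' @param path input file.
#' @param units unit label for the values (`"label"` for mask volumes).
#' @return A [dose_grid()].
#' @export
read_volume <- function(path, units = "mGy/MU") {
  lower <- tolower(path)
  if (endsWith(lower, ".3ddose")) return(read_3ddose(path, units = units))
  if (endsWith(lower, ".nii") || endsWith(lower, ".nii.gz")) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vals)) != 3L)
      .stopf("format error in %s: expected a 3D volume", path)
    xf <- RNifti::xform(img)
    # voxel size from the affine column norms; fall back to pixdim
    spacing_mm <- sqrt(colSums(xf[1:3, 1:3]^2))
    if (any(spacing_mm <= 0)) spacing_mm <- RNifti::pixdim(img)[1:3]
    origin_mm <- xf[1:3, 4]
    return(dose_grid(vals, spacing_mm / 10, origin_mm / 10, units = units))
  }
  .stopf("format error: unsupported volume format: %s (supported: .3ddose, .nii, .nii.gz)",
         path)
}

#' Write a dose grid as a NIfTI volume
#'
#' Geometry is written as a diagonal affine in mm.
#'
#' @param grid a [dose_grid()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  lower <- tolower(path)
  if (endsWith(lower, ".3ddose")) return(write_3ddose(grid, path))
  if (!(endsWith(lower, ".nii") || endsWith(lower, ".nii.gz")))
    .stopf("format error: unsupported output format: %s", path)
  aff <- diag(c(grid$spacing * 10, 1))
  aff[1:3, 4] <- grid$origin * 10
  img <- RNifti::asNifti(grid$values,
                         reference = list(pixdim = c(-1, grid$spacing * 10,
                                                     1, 1, 1, 1)))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write an organ label volume with a JSON name table
#'
#' The label volume is an integer volume (0 = background); the sidecar
#' JSON maps label integers to organ names.
#'
#' @param path label volume path (`.nii`/`.nii.gz`).
#' @param sidecar JSON name-table path; defaults to `<path>.labels.json`.
#' @return For the reader, a list with `labels` (a [dose_grid()] with
#'   `units = "label"`) and `names` (named character vector, names are
#'   the label integers).
#' @export
read_label_volume <- function(path, sidecar = NULL) {
  grid <- read_volume(path, units = "label")
  grid$values <- array(as.integer(round(grid$values)), dim = dim(grid$values))
  if (is.null(sidecar)) sidecar <- paste0(path, ".labels.json")
  nm <- character(0)
  if (file.exists(sidecar)) {
    tab <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nm <- unlist(tab)
  }
  list(labels = grid, names = nm)
}

#' @rdname read_label_volume
#' @param grid integer label [dose_grid()] to write.
#' @param names named character vector mapping label integers to organ
#'   names.
#' @export
write_label_volume <- function(grid, path, names = NULL, sidecar = NULL) {
  write_volume(grid, path)
  if (!is.null(names)) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".labels.json")
    jsonlite::write_json(as.list(names), sidecar, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Extract one organ mask from a label volume
#'
#' @param labels result of [read_label_volume()] or a label [dose_grid()].
#' @param label integer label or organ name (when a name table is
#'   attached).
#' @return Logical 3D array.
#' @export
organ_mask <- function(labels, label) {
  nm <- NULL
  if (is.list(labels) && !inherits(labels, "dose_grid")) {
    nm <- labels$names
    labels <- labels$labels
  }
  stopifnot(inherits(labels, "dose_grid"))
  if (is.character(label)) {
    if (is.null(nm) || !label %in% nm)
      .stopf("invalid input: organ name '%s' not in the label table", label)
    label <- as.integer(names(nm)[match(label, nm)])
  }
  labels$values == label
}

#' Read a JSON plan summary
#'
#' Plan-level inputs: prescription (mGy), total MU, field area `F_U`
#' (cm^2, or the string `"derive"` to extract it from a dose volume),
#' optional leakage `L_u` (mGy/MU), isocenter (cm) and axis map.
#'
#' @param path JSON file.
#' @return A list with validated fields: `prescription`, `total_MU`,
#'   `F_U`, `L_u`, `isocenter`, `axis_map`.
#' @export
read_plan_summary <- function(path) {
  if (!file.exists(path)) .stopf("format error: plan file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("prescription", "total_MU", "isocenter")
  miss <- setdiff(need, names(p))
  if (length(miss)) .stopf("format error in %s: missing plan field '%s'",
                           path, miss[1])
  .check_scalar(p$prescription, "prescription")
  .check_scalar(p$total_MU, "total_MU")
  if (length(p$isocenter) != 3L)
    .stopf("format error in %s: 'isocenter' must have 3 components", path)
  if (is.null(p$axis_map)) p$axis_map <- c(1, 2, 3)
  if (is.null(p$L_u)) p$L_u <- .peridose_defaults$L_r
  if (is.null(p$F_U)) p$F_U <- "derive"
  p
}
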