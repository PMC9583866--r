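# Shared fixtures: small grids and reference-conditions parameters.

# reference-style plan: epsilon = F = 1, L_u = L_r
ref_params <- function() {
  treatment_parameters(prescription = 2000, total_MU = 278, F_U = 149.2)
}

# cube centered on the isocenter: n^3 voxels, given spacing (cm)
centered_grid <- function(n, spacing, values = array(0, dim = c(n, n, n))) {
  dose_grid(values, rep(spacing, 3), rep(-(n - 1) / 2 * spacing, 3))
}

centered_frame <- function() isocenter_frame(c(0, 0, 0))

# noiseless model cube on a centered grid, zeros inside r_min
model_cube_values <- function(n, spacing, params = ref_params(),
                              ref = reference_constants(),
                              coeffs = model_coefficients()) {
  g <- centered_grid(n, spacing)
  co <- voxel_coords_in_model_frame(g, centered_frame())
  v <- array(0, dim = dim(g$values))
  out <- co$r >= ref$r_min
  v[out] <- ppd_at_point(co$x[out], co$y[out], co$z[out], params, ref, coeffs)
  list(grid = dose_grid(v, g$spacing, g$origin), coords = co)
}

# brute-force 6-connectivity erosion oracle (triple loop)
erode6_brute <- function(m) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    ok <- TRUE
    for (del in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      p <- c(i, j, k) + del
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  out
}
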