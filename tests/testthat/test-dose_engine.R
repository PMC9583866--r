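test_that("voxel coordinates map into the isocenter frame correctly", {
  g <- dose_grid(array(0, dim = c(5, 5, 5)), c(1, 1, 1), c(0, 0, 0))
  fr <- isocenter_frame(c(2, 2, 2))  # a voxel center
  co <- voxel_coords_in_model_frame(g, fr)
  expect_equal(co$x[3, 3, 3], 0)
  expect_equal(co$y[3, 3, 3], 0)
  expect_equal(co$z[3, 3, 3], 0)
  expect_equal(co$r[3, 3, 3], 0)
  # identity map, unit spacing, origin isocenter: coordinates = index offsets
  fr0 <- isocenter_frame(c(0, 0, 0))
  co0 <- voxel_coords_in_model_frame(g, fr0)
  expect_equal(co0$x[4, 1, 1], 3)
  expect_equal(co0$y[1, 5, 1], 4)
  expect_equal(co0$z[1, 1, 2], 1)
  # flipping the craniocaudal sign changes z but not |z| or r
  co_f <- voxel_coords_in_model_frame(g, isocenter_frame(c(2, 2, 2),
                                                         c(1, 2, -3)))
  expect_equal(abs(co_f$z), abs(co$z))
  expect_equal(co_f$r, co$r)
  # axis permutation: model x along grid axis 2
  co_p <- voxel_coords_in_model_frame(g, isocenter_frame(c(2, 2, 2),
                                                         c(2, 1, 3)))
  expect_equal(co_p$x, co$y)
  expect_equal(co_p$y, co$x)
  expect_error(isocenter_frame(c(0, 0, 0), c(1, 1, 3)), "configuration error")
})

test_that("the dose cube matches the point model voxel by voxel", {
  p <- ref_params()
  g <- centered_grid(9, 5)  # spans +/-20 cm
  fr <- centered_frame()
  cube <- compute_ppd_cube(g, fr, p)
  co <- voxel_coords_in_model_frame(g, fr)
  for (idx in list(c(1, 1, 1), c(9, 5, 3), c(5, 5, 9), c(2, 7, 4))) {
    i <- idx[1]; j <- idx[2]; k <- idx[3]
    expect_equal(cube$values[i, j, k],
                 ppd_at_point(co$x[i, j, k], co$y[i, j, k], co$z[i, j, k], p))
  }
  # voxels inside r_min are sentinels with valid = FALSE
  expect_true(is.na(cube$values[5, 5, 5]))
  expect_false(cube$valid[5, 5, 5])
  expect_true(all(is.finite(cube$values[cube$valid])))
})

test_that("corner voxels of a coarse cube equal the hand evaluation", {
  p <- ref_params()
  g <- centered_grid(3, 10)
  cube <- compute_ppd_cube(g, centered_frame(), p)
  r <- sqrt(300)
  hand <- (37.890 - 0.679 * 10) * exp(-0.007 * r) / 300
  expect_equal(cube$values[1, 1, 1], hand, tolerance = 1e-12)
  expect_equal(cube$values[3, 3, 3], hand, tolerance = 1e-12)
})

test_that("cubes respect exclusion masks and the leakage plateau", {
  p <- ref_params()
  g <- centered_grid(3, 10)
  excl <- array(TRUE, dim = c(3, 3, 3))
  cube <- compute_ppd_cube(g, centered_frame(), p, exclusion_mask = excl)
  expect_true(all(is.na(cube$values)))
  expect_false(any(cube$valid))
  # a grid entirely beyond r_cut is a uniform leakage plateau
  far <- dose_grid(array(0, dim = c(3, 3, 3)), c(2, 2, 2), c(50, 50, 50))
  p2 <- treatment_parameters(2000, 278, F_U = 149.2, L_u = 0.0032)
  cube_far <- compute_ppd_cube(far, centered_frame(), p2)
  expect_true(all(cube_far$values == 0.0032))
})

test_that("cube values are invariant under axis relabelling that fixes the craniocaudal axis", {
  p <- ref_params()
  g <- centered_grid(7, 6)
  c1 <- compute_ppd_cube(g, isocenter_frame(c(0, 0, 0), c(1, 2, 3)), p)
  c2 <- compute_ppd_cube(g, isocenter_frame(c(0, 0, 0), c(2, 1, 3)), p)
  c3 <- compute_ppd_cube(g, isocenter_frame(c(0, 0, 0), c(-1, 2, -3)), p)
  expect_equal(c1$values, c2$values)
  expect_equal(c1$values, c3$values)
})

test_that("the in-field mask thresholds on the interpolated isocenter dose", {
  v <- array(0, dim = c(7, 7, 7))
  v[4, 4, 4] <- 100
  v[3, 4, 4] <- 60
  v[4, 3, 4] <- 4.9
  g <- dose_grid(v, c(1, 1, 1), c(-3, -3, -3))
  fr <- centered_frame()
  m <- in_field_mask(g, fr, 0.05)
  expect_true(m[4, 4, 4])
  expect_true(m[3, 4, 4])
  expect_false(m[4, 3, 4])
  # uniform cube: everything is in-field
  gu <- dose_grid(array(2, dim = c(3, 3, 3)), c(1, 1, 1), c(-1, -1, -1))
  expect_true(all(in_field_mask(gu, fr, 0.05)))
  # monotone in the fraction
  set.seed(3)
  gv <- dose_grid(array(runif(343, 0, 1), dim = c(7, 7, 7)) +
                    ifelse(v > 0, v, 0), c(1, 1, 1), c(-3, -3, -3))
  m05 <- in_field_mask(gv, fr, 0.05)
  m50 <- in_field_mask(gv, fr, 0.50)
  expect_true(all(m05[m50]))
  expect_error(in_field_mask(dose_grid(array(0, dim = c(3, 3, 3)),
                                       c(1, 1, 1), c(-1, -1, -1)), fr),
               "invalid input")
})

test_that("the in-field ball of a spherically decaying dose matches its analytic crossing", {
  # dose = exp(-r^2 / (2 sigma^2)): the 5% isodose radius is
  # sigma * sqrt(2 ln 20)
  sigma <- 4
  n <- 33
  g <- centered_grid(n, 1)
  co <- voxel_coords_in_model_frame(g, centered_frame())
  g$values <- exp(-co$r^2 / (2 * sigma^2))
  m <- in_field_mask(g, centered_frame(), 0.05)
  r_threshold <- sigma * sqrt(2 * log(20))
  expect_true(all(co$r[m] <= r_threshold + 1))
  expect_true(all(co$r[!m] >= r_threshold - 1))
})

test_that("body interior erosion matches the brute-force oracle", {
  solid3 <- array(TRUE, dim = c(3, 3, 3))
  e3 <- body_interior_mask(solid3)
  expect_equal(sum(e3), 1L)
  expect_true(e3[2, 2, 2])
  empty <- array(FALSE, dim = c(4, 4, 4))
  expect_equal(body_interior_mask(empty), empty)
  solid5 <- array(TRUE, dim = c(5, 5, 5))
  e5 <- body_interior_mask(solid5)
  expect_equal(sum(e5), 27L)
  expect_true(all(e5[2:4, 2:4, 2:4]))
  set.seed(21)
  rnd <- array(runif(6 * 7 * 5) > 0.4, dim = c(6, 7, 5))
  expect_equal(body_interior_mask(rnd), erode6_brute(rnd))
})

test_that("trilinear interpolation is exact on linear fields", {
  n <- 5
  g <- centered_grid(n, 2)
  co <- voxel_coords_in_model_frame(g, centered_frame())
  g$values <- 1 + 2 * co$x - 0.5 * co$y + 0.25 * co$z
  f <- function(p) 1 + 2 * p[1] - 0.5 * p[2] + 0.25 * p[3]
  for (pt in list(c(0, 0, 0), c(0.7, -1.3, 2.1), c(-3.9, 3.9, 0.5))) {
    expect_equal(interp_at_point(g, pt), f(pt), tolerance = 1e-12)
  }
  expect_error(interp_at_point(g, c(50, 0, 0)), "outside the grid")
})
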