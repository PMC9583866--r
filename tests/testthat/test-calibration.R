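test_that("the calibration mask combines body interior, in-field, and radius rules", {
  ph <- generate_phantom()
  rd <- generate_reference_dose(ph, noise_cv = 0, seed = 1L)
  ref <- reference_constants()
  mask <- calibration_mask(rd, ph$frame, ph$body)
  co <- voxel_coords_in_model_frame(rd, ph$frame)
  interior <- body_interior_mask(ph$body)
  infield <- in_field_mask(rd, ph$frame, 0.05)
  # in-field blob voxels excluded by construction
  expect_false(any(mask & infield))
  # the mask stays inside the eroded body and the 40 cm shell
  expect_true(all(interior[mask]))
  expect_true(all(co$r[mask] <= ref$r_cut))
  expect_true(all(co$r[mask] >= ref$r_min))
  expect_gt(sum(mask), 500)
  # voxels beyond r_cut are excluded even when inside the body: shrink the
  # cutoff so the outer body shell drops out
  ref35 <- reference_constants(r_cut = 35)
  mask35 <- calibration_mask(rd, ph$frame, ph$body, ref35)
  expect_false(any(co$r[mask35] > 35))
  expect_lt(sum(mask35), sum(mask))
  # an empty mask is a hard error
  expect_error(calibration_mask(rd, ph$frame, array(FALSE, dim = dim(rd$values))),
               "fit infeasible")
})

test_that("noiseless parameter recovery holds from perturbed starts", {
  p <- ref_params()
  mc <- model_cube_values(21, 4)  # +/-40 cm at 4 cm spacing
  mask <- mc$coords$r >= 8 & mc$coords$r <= 40
  fr <- centered_frame()
  truth <- c(37.890, 0.679, 0.007)
  set.seed(5)
  for (trial in 1:3) {
    start <- truth * runif(3, 0.5, 1.5)
    fit <- fit_coefficients(mc$grid, mask, fr, start = start)
    got <- unlist(fit$coefficients)
    expect_lt(max(abs(got - truth) / truth), 1e-3)
    expect_true(fit$converged)
  }
  expect_error(fit_coefficients(mc$grid, array(FALSE, dim = dim(mc$grid$values)), fr),
               "fit infeasible")
})

test_that("absolute-loss fitting also recovers the generating coefficients", {
  mc <- model_cube_values(21, 4)
  mask <- mc$coords$r >= 8 & mc$coords$r <= 40
  fit <- fit_coefficients(mc$grid, mask, centered_frame(), loss = "absolute")
  truth <- c(37.890, 0.679, 0.007)
  expect_lt(max(abs(unlist(fit$coefficients) - truth) / truth), 1e-2)
})

test_that("agreement statistics match trivial cases and a brute-force oracle", {
  v <- array(runif(27, 1, 2), dim = c(3, 3, 3))
  g <- dose_grid(v, c(1, 1, 1), c(0, 0, 0))
  same <- agreement_stats(g, g)
  expect_equal(same$p95_abs_pct_diff, 0)
  expect_equal(same$mean_abs_pct_diff, 0)
  expect_equal(same$max_abs_diff, 0)
  g11 <- dose_grid(v * 1.1, c(1, 1, 1), c(0, 0, 0))
  up <- agreement_stats(g11, g)
  expect_equal(up$p95_abs_pct_diff, 10)
  expect_equal(up$mean_abs_pct_diff, 10)
  expect_equal(up$max_abs_diff, 0.1 * max(v))
  # 20-voxel crafted case against a direct recomputation
  set.seed(9)
  ref_v <- runif(20, 0.5, 5)
  mod_v <- ref_v * (1 + rnorm(20, 0, 0.2))
  arr_r <- array(c(ref_v, rep(1, 7)), dim = c(3, 3, 3))
  arr_m <- array(c(mod_v, rep(1, 7)), dim = c(3, 3, 3))
  mask <- array(c(rep(TRUE, 20), rep(FALSE, 7)), dim = c(3, 3, 3))
  st <- agreement_stats(dose_grid(arr_m, c(1, 1, 1), c(0, 0, 0)),
                        dose_grid(arr_r, c(1, 1, 1), c(0, 0, 0)), mask)
  pct <- 100 * abs(mod_v - ref_v) / ref_v
  expect_equal(st$mean_abs_pct_diff, mean(pct))
  expect_equal(st$p95_abs_pct_diff, unname(quantile(pct, 0.95)))
  expect_equal(st$max_abs_diff, max(abs(mod_v - ref_v)))
  expect_equal(st$n, 20L)
  # scale invariance under common rescaling
  st2 <- agreement_stats(dose_grid(arr_m * 7, c(1, 1, 1), c(0, 0, 0)),
                         dose_grid(arr_r * 7, c(1, 1, 1), c(0, 0, 0)), mask)
  expect_equal(st2$mean_abs_pct_diff, st$mean_abs_pct_diff)
  expect_equal(st2$p95_abs_pct_diff, st$p95_abs_pct_diff)
  expect_error(agreement_stats(dose_grid(arr_m, c(1, 1, 1), c(0, 0, 0)),
                               dose_grid(array(0, dim = c(3, 3, 3)),
                                         c(1, 1, 1), c(0, 0, 0))),
               "invalid input")
})

test_that("point-dose comparison reproduces the published worst-case differences", {
  # prostate validation: one point predicted 31.4, measured 47.2 mGy/Gy
  st <- compare_point_doses(c(31.4), c(47.2))
  expect_equal(st$max_abs_diff, 15.8)
  # lung stress test: predicted 14.1, simulated 49.0 mGy/Gy
  st2 <- compare_point_doses(c(14.1), c(49.0))
  expect_equal(st2$max_abs_diff, 34.9)
  st3 <- compare_point_doses(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st3$mean_abs_pct_diff, 0)
  expect_equal(st3$max_abs_diff, 0)
  expect_error(compare_point_doses(c(1, 2), c(1, 2, 3)), "lengths differ")
  # per-point table carries coordinates when given
  pred <- data.frame(x = c(0, 10), y = c(5, 0), z = c(20, -15),
                     value = c(1.0, 2.0))
  meas <- data.frame(x = c(0, 10), y = c(5, 0), z = c(20, -15),
                     value = c(1.1, 1.8))
  st4 <- compare_point_doses(pred, meas)
  expect_equal(nrow(st4$per_point), 2L)
  expect_equal(st4$per_point$abs_diff, c(0.1, 0.2), tolerance = 1e-12)
  expect_true(all(c("x", "y", "z") %in% names(st4$per_point)))
})

test_that("weighted fitting accepts an inverse-variance array", {
  mc <- model_cube_values(13, 6)
  mask <- mc$coords$r >= 8 & mc$coords$r <= 36
  w <- array(1, dim = dim(mc$grid$values))
  fit <- fit_coefficients(mc$grid, mask, centered_frame(), weights = w)
  truth <- c(37.890, 0.679, 0.007)
  expect_lt(max(abs(unlist(fit$coefficients) - truth) / truth), 1e-3)
})
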