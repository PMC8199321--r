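test_that("requirement angles are the five-point grid over the motion range", {
  expect_equal(requirement_angles(110), c(0, 27.5, 55, 82.5, 110))
  expect_equal(requirement_angles(100), c(0, 25, 50, 75, 100))
  expect_equal(requirement_angles(70), c(0, 17.5, 35, 52.5, 70))
  p <- default_primitives()
  expect_equal(
    requirement_angles(p[p$id == "finger_pip_flexion", ]),
    c(0, 27.5, 55, 82.5, 110)
  )
})

test_that("calibration summaries report sample mean, SD, and normalized error", {
  rec <- data.frame(
    participant = rep(c("S01", "S02", "S03"), 2),
    primitive = "toy",
    actual_angle = rep(c(0, 50), each = 3),
    measured_angle = c(5, 5, 5, 49, 50, 51)
  )
  s <- summarize_calibration(rec, rom_spans = c(toy = 50))
  expect_equal(s$mean_measured, c(5, 50))
  expect_equal(s$sd_measured, c(0, 1))
  expect_equal(s$normalized_error, c(0.1, 0))

  expect_equal(sd(c(1, 2, 3)), 1) # sample SD convention used throughout
  three <- summarize_calibration(data.frame(
    participant = c("a", "b", "c"), primitive = "t",
    actual_angle = 0, measured_angle = c(1, 2, 3)
  ), rom_spans = c(t = 10))
  expect_equal(three$mean_measured, 2)
  expect_equal(three$sd_measured, 1)
})

test_that("normalized error is the absolute deviation over the motion span", {
  expect_equal(normalized_error(40, 40, 80), 0)
  expect_equal(normalized_error(40.7, 80, 80), 0.491, tolerance = 1e-3)
  expect_equal(normalized_error(77.0, 110, 110), 0.3)
  # scale invariance
  expect_equal(normalized_error(30, 50, 100), normalized_error(60, 100, 200))
})

test_that("published summary statistics hold in the calibration reference", {
  ref <- calibration_reference()
  worst <- ref[which.max(ref$sd_measured), ]
  expect_equal(worst$sd_measured, 16.1)
  expect_equal(worst$primitive, "finger_pip_flexion")
  expect_equal(worst$actual_angle, 55)
  expect_true(all(ref$sd_measured[ref$sd_measured != 16.1] <= 12))
})

test_that("affine fits agree with the closed-form oracle and the printed coefficients", {
  actual <- c(0, 22.5, 45, 67.5, 90)
  measured <- c(5.0, 24.7, 40.4, 57.6, 76.9)
  m <- fit_mapping(actual, measured, "finger_mcp_flexion")
  o <- ols_oracle(actual, measured)
  expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(m$slope, o$slope, tolerance = 1e-10)
  expect_equal(m$slope, 0.78, tolerance = 0.02)
  expect_equal(m$intercept, 5.63, tolerance = 0.15)

  ideal <- fit_mapping(c(0, 25, 50, 75), c(0, 25, 50, 75))
  expect_equal(ideal$intercept, 0, tolerance = 1e-10)
  expect_equal(ideal$slope, 1, tolerance = 1e-10)
  expect_equal(ideal$r_squared, 1)

  wx <- fit_mapping(
    c(0, 17.5, 35, 52.5, 70), c(8.2, 24.3, 32.7, 43.6, 48.5),
    "wrist_extension"
  )
  expect_equal(wx$intercept, 11.48, tolerance = 0.15)
  expect_equal(wx$slope, 0.57, tolerance = 0.02)
})

test_that("cell-mean and raw-record fits coincide under a balanced design", {
  set.seed(7)
  actual <- rep(c(0, 25, 50, 75, 100), each = 10)
  measured <- 3 + 0.8 * actual + rnorm(50, 0, 6)
  raw <- fit_mapping(actual, measured)
  cellm <- tapply(measured, actual, mean)
  agg <- fit_mapping(as.numeric(names(cellm)), as.numeric(cellm))
  expect_equal(raw$intercept, agg$intercept, tolerance = 1e-9)
  expect_equal(raw$slope, agg$slope, tolerance = 1e-9)
})

test_that("the finger-abduction sign policy fits magnitudes", {
  ref <- calibration_reference()
  ab <- ref[ref$primitive == "finger_abduction", ]
  m <- fit_mapping(ab$actual_angle, ab$mean_measured, "finger_abduction",
    sign_policy = "magnitude"
  )
  expect_gt(m$slope, 0)
  expect_equal(m$slope, 0.78, tolerance = 0.02)
  expect_equal(m$intercept, 6.32, tolerance = 0.15)
})

test_that("segmentation transfer applies the mapping and opens the extremes", {
  seg <- reference_segmentation("real")$finger_mcp_flexion
  m <- structure(
    list(
      primitive = "finger_mcp_flexion", intercept = 5.63, slope = 0.78,
      r_squared = 1, n_points = 5L, sign_policy = "keep"
    ),
    class = "affine_mapping"
  )
  dev <- map_segmentation(seg, m)
  expect_equal(dev$boundaries[1], 5.63 + 0.78 * 22.4, tolerance = 1e-9)
  expect_equal(dev$boundaries[1], 23.10, tolerance = 0.005)
  expect_true(dev$open_ended)
  expect_equal(dev$n_states, seg$n_states)

  ident <- structure(
    list(
      primitive = "finger_mcp_flexion", intercept = 0, slope = 1,
      r_squared = 1, n_points = 5L, sign_policy = "keep"
    ),
    class = "affine_mapping"
  )
  same <- map_segmentation(seg, ident)
  expect_equal(same$boundaries, seg$boundaries)

  other <- structure(
    list(primitive = "thumb_ip_flexion", intercept = 0, slope = 1),
    class = "affine_mapping"
  )
  expect_error(map_segmentation(seg, other), "different primitives")
})

test_that("mapping inversion round-trips and rejects zero slope", {
  m <- structure(
    list(primitive = "x", intercept = 5.63, slope = 0.78),
    class = "affine_mapping"
  )
  expect_equal(invert_mapping(m, 5.63 + 0.78 * 22.4), 22.4, tolerance = 1e-9)
  for (x in c(-10, 0, 45.2, 110)) {
    expect_equal(invert_mapping(m, m$intercept + m$slope * x), x,
      tolerance = 1e-9
    )
  }
  zero <- structure(
    list(primitive = "x", intercept = 1, slope = 0),
    class = "affine_mapping"
  )
  expect_error(invert_mapping(zero, 3), "zero")
})

test_that("calibration recovery: fitted coefficients within two standard errors", {
  dm <- device_model("finger_mcp_flexion", 5.63, 0.78, 90, noise_sd = 10)
  cal <- simulate_calibration(dm, n_subjects = 10, seed = 23)
  m <- fit_mapping(cal$actual_angle, cal$measured_angle, "finger_mcp_flexion")
  se <- summary(lm(measured_angle ~ actual_angle, data = cal))$coefficients[, "Std. Error"]
  expect_lt(abs(m$intercept - 5.63), 2 * se[1])
  expect_lt(abs(m$slope - 0.78), 2 * se[2])
})

test_that("normalized error grows with angle under an attenuating device", {
  dm <- device_model("toy", 0, 0.68, 100, noise_sd = 0)
  cal <- simulate_calibration(dm, n_subjects = 3, seed = 1)
  s <- summarize_calibration(cal, rom_spans = c(toy = 100))
  expect_true(all(diff(s$normalized_error[order(s$actual_angle)]) >= 0))
})
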