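test_that("probit transform matches the inverse-normal and excludes extremes", {
  expect_equal(proportion_to_z(0.5), 0)
  expect_equal(round(proportion_to_z(0.75), 2), 0.67)
  expect_equal(proportion_to_z(0.75), qnorm(0.75), tolerance = 1e-12)
  expect_equal(proportion_to_z(0.9), 1.2816, tolerance = 1e-4)
  expect_equal(proportion_to_z(0.25), -0.6745, tolerance = 1e-4)
  expect_true(is.na(proportion_to_z(0)))
  expect_true(is.na(proportion_to_z(1)))
  expect_equal(z_criterion(), qnorm(0.75))
})

test_that("probit and its inverse round-trip to 1e-9 over [-3, 3]", {
  z <- seq(-3, 3, by = 0.0625)
  expect_equal(proportion_to_z(z_to_proportion(z)), z, tolerance = 1e-9)
})

test_that("judgments pool across participants and swaps before the proportion", {
  cell <- expand.grid(
    participant = sprintf("P%02d", 1:20), swap = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  cell$primitive <- "toy"
  cell$standard_kind <- "boundary_low"
  cell$standard_angle <- 0
  cell$contrast_angle <- 10
  cell$response <- rep(c("different", "same"), c(30, 10))
  pts <- aggregate_judgments(cell)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$n_total, 40L)
  expect_equal(pts$proportion, 0.75)
  expect_equal(pts$z, qnorm(0.75))

  cell$response <- "same"
  all_same <- aggregate_judgments(cell)
  expect_equal(all_same$proportion, 0)
  expect_true(is.na(all_same$z))

  cell4 <- cell[1:4, ]
  cell4$response <- c("different", "same", "same", "same")
  expect_equal(aggregate_judgments(cell4)$z, qnorm(0.25), tolerance = 1e-9)

  # continuity correction keeps extreme cells instead of dropping them
  corrected <- aggregate_judgments(cell, correction = TRUE)
  expect_equal(corrected$z, qnorm(1 / 80))

  cell$response <- "maybe"
  expect_error(aggregate_judgments(cell), "same.*different")
})

test_that("least-squares fit agrees with the closed-form oracle", {
  expect_equal(fit_line(c(0, 1), c(0, 1))[c("intercept", "slope")],
    list(intercept = 0, slope = 1),
    tolerance = 1e-12
  )
  f <- fit_line(c(0, 1, 2), c(1, 2, 2))
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 7 / 6, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- fit_line(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
  expect_error(fit_line(c(1, 1), c(0, 2)), "distinct")
})

test_that("curve intersection solves the two linear equations", {
  c1 <- curve_from_coefs(-0.5, 0.02)
  c2 <- curve_from_coefs(1.7, -0.02, standard_kind = "boundary_high", standard_angle = 110)
  hit <- intersect_curves(c1, c2)
  expect_equal(hit$angle, 55)
  expect_equal(hit$z, 0.6)

  # symmetric curves intersect at half range
  a <- curve_from_coefs(-1, 0.03)
  b <- curve_from_coefs(-1 + 0.03 * 100, -0.03)
  expect_equal(intersect_curves(a, b)$angle, 50)

  expect_error(intersect_curves(c1, c1), "parallel")
  c3 <- curve_from_coefs(0, 0.05, primitive = "other")
  expect_error(intersect_curves(c1, c3), "different primitives")
})

test_that("curve maximum is the fitted value at the endpoint opposite the standard", {
  rom <- c(0, 110)
  low <- curve_from_coefs(-0.5, 0.02, standard_kind = "boundary_low")
  expect_equal(curve_max(low, rom), 1.7)
  high <- curve_from_coefs(1.7, -0.02, standard_kind = "boundary_high")
  expect_equal(curve_max(high, rom), 1.7)
  flat <- curve_from_coefs(0.4, 0, standard_kind = "boundary_low")
  expect_equal(curve_max(flat, rom), 0.4)
  below <- curve_from_coefs(1.2, -0.02, standard_kind = "median_below")
  expect_equal(curve_max(below, rom), 1.2)
})

test_that("round-1 decision tree separates one, two, and more-than-two states", {
  rom <- c(0, 100)
  # both maxima far below the criterion: a single state
  low <- curve_from_coefs(-1, 0.013, standard_kind = "boundary_low")
  high <- curve_from_coefs(0.3, -0.013, standard_kind = "boundary_high")
  s1 <- segment_round1(low, high, rom)
  expect_s3_class(s1, "segmentation")
  expect_equal(s1$n_states, 1L)
  expect_length(s1$boundaries, 0L)

  # maxima above, median Z below: two states at the median
  low <- curve_from_coefs(-1, 0.025, standard_kind = "boundary_low")
  high <- curve_from_coefs(-1 + 0.025 * 100, -0.025, standard_kind = "boundary_high")
  s2 <- segment_round1(low, high, rom)
  expect_equal(s2$n_states, 2L)
  expect_equal(s2$boundaries, 50)
  expect_equal(s2$median_angle, 50)

  # median Z above the criterion: flagged for the median-standard round
  low <- curve_from_coefs(-1, 0.045, standard_kind = "boundary_low")
  high <- curve_from_coefs(-1 + 0.045 * 100, -0.045, standard_kind = "boundary_high")
  s3 <- segment_round1(low, high, rom)
  expect_equal(s3$status, "round2_required")
  expect_equal(s3$median_angle, 50)
})

test_that("round-2 places boundaries at the median/boundary curve intersections", {
  rom <- c(0, 100)
  low <- curve_from_coefs(-1, 0.045, standard_kind = "boundary_low")
  high <- curve_from_coefs(-1 + 0.045 * 100, -0.045, standard_kind = "boundary_high")
  s3 <- segment_round1(low, high, rom)

  # symmetric median curves: boundaries symmetric about the median
  mb <- curve_from_coefs(-1 + 0.06 * 50, -0.06, standard_kind = "median_below")
  ma <- curve_from_coefs(-1 - 0.06 * 50, 0.06, standard_kind = "median_above")
  s <- segment_round2(s3, low, high, mb, ma)
  expect_equal(s$n_states, 3L)
  expect_equal(diff(c(s$boundaries[1], 50)), diff(c(50, s$boundaries[2])),
    tolerance = 1e-9
  )
  expect_true(all(s$boundaries > rom[1] & s$boundaries < rom[2]))

  # median curves that never clear the criterion fall back to two states
  weak_mb <- curve_from_coefs(-1 + 0.01 * 50, -0.01, standard_kind = "median_below")
  weak_ma <- curve_from_coefs(-1 - 0.01 * 50, 0.01, standard_kind = "median_above")
  s_weak <- segment_round2(s3, low, high, weak_mb, weak_ma)
  expect_equal(s_weak$n_states, 2L)
  expect_equal(s_weak$boundaries, 50)

  expect_error(segment_round2(s, low, high, mb, ma), "round2_required")
})

test_that("an intersection outside the aROM flags the primitive, never clamps", {
  rom <- c(0, 100)
  low <- curve_from_coefs(-0.2, 0.03, standard_kind = "boundary_low")
  # high curve rises so steeply the intersection lands below the rom
  high <- curve_from_coefs(8, -0.05, standard_kind = "boundary_high")
  s <- segment_round1(low, high, rom)
  expect_equal(s$status, "unresolvable")
  expect_length(s$boundaries, 0L)
  expect_match(s$provenance, "outside the aROM")
})

test_that("full pipeline recovers the generating state count and boundaries", {
  p <- default_primitives()
  s1 <- build_exp1_schedule(seed = 5)
  s2 <- build_exp2_schedule(
    p[p$id == "finger_pip_flexion", ],
    medians = c(finger_pip_flexion = 55), seed = 6
  )
  om <- observer_model("finger_pip_flexion", c(0, 110), 3, c(30, 80))
  j1 <- simulate_judgments(om, s1, n_participants = 20, seed = 11)
  j2 <- simulate_judgments(om, s2, n_participants = 20, seed = 12)
  seg <- segment_primitive(j1, j2, "finger_pip_flexion")
  expect_equal(seg$status, "resolved")
  expect_equal(seg$n_states, 3L)
  expect_equal(seg$boundaries, c(30, 80), tolerance = 5 / 30)
  expect_true(all(abs(seg$boundaries - c(30, 80)) <= 5))
  expect_true(all(seg$boundaries > 0 & seg$boundaries < 110))
})
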