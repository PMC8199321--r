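test_that("state-count reconciliation keeps the perceptual count", {
  r <- reconcile_counts(2, c(3, 3, 3, 2, 3), surplus_at_extreme = TRUE)
  expect_equal(r$final_n, 2L)
  expect_match(r$note, "extreme")

  r2 <- reconcile_counts(3, rep(3, 20))
  expect_equal(r2$final_n, 3L)
  expect_match(r2$note, "agrees")

  expect_equal(reconcile_counts(1, rep(1, 20))$final_n, 1L)
  expect_equal(sum(reconcile_counts(2, c(3, 3, 2))$distribution), 3)
  expect_error(reconcile_counts(2, integer(0)), "empty")
})

test_that("ICC(2,1) matches the sums-of-squares oracle", {
  m <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2)
  got <- icc_two_rater(m)
  expect_equal(got$icc_value, icc21_oracle(m), tolerance = 1e-10)

  set.seed(99)
  for (i in 1:10) {
    n <- sample(4:15, 1)
    mm <- matrix(rnorm(2 * n, mean = 40, sd = 8), ncol = 2)
    mm[, 2] <- mm[, 1] + rnorm(n, 0, 2)
    expect_equal(icc_two_rater(mm)$icc_value, icc21_oracle(mm),
      tolerance = 1e-9
    )
  }
})

test_that("ICC is exactly 1 for identical raters and undefined for constant data", {
  m <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(icc_two_rater(m)$icc_value, 1.0, tolerance = 1e-12)

  const <- icc_two_rater(matrix(0, nrow = 20, ncol = 2))
  expect_true(is.na(const$icc_value))
  expect_match(const$notes, "constant")

  expect_error(icc_two_rater(matrix(1:4, ncol = 2)), "3 subjects")
})

test_that("synthetic two-rater data with small rater noise yields ICC above 0.9", {
  pm <- performer_model("thumb_ip_flexion", c(0, 74), c(0, 80),
    subject_sd = 8, rater_sd = 1
  )
  ex <- simulate_executions(pm, n_participants = 20, seed = 31)
  st <- ex[ex$state_index == 2, ]
  icc <- icc_two_rater(cbind(st$angle_rater1, st$angle_rater2))
  expect_gt(icc$icc_value, 0.9)
})

test_that("feature angle removes Tukey-fence outliers and reports whole degrees", {
  plain <- feature_angle(c(48, 50, 51, 52, 54))
  expect_equal(plain$reported, 51)
  expect_length(plain$removed, 0L)

  with_outlier <- feature_angle(c(49, 50, 51, 51, 52, 53, 120))
  expect_equal(with_outlier$removed, 120)
  expect_equal(with_outlier$reported, 51)
  expect_equal(with_outlier$mean, 51)

  same <- feature_angle(rep(38, 6))
  expect_equal(same$reported, 38)
  expect_length(same$removed, 0L)

  expect_error(feature_angle(numeric(0)), "no finite values")
})

test_that("feature angles recover the generating typical angles at n = 20", {
  typicals <- c(0, 40, 74)
  pm <- performer_model("finger_mcp_flexion", typicals, c(0, 90),
    subject_sd = 5, rater_sd = 1
  )
  ex <- simulate_executions(pm, n_participants = 20, seed = 17)
  ex$angle <- (ex$angle_rater1 + ex$angle_rater2) / 2
  for (s in seq_along(typicals)) {
    fa <- feature_angle(ex$angle[ex$state_index == s])
    # truncation at the aROM floor biases the first state upward slightly
    expect_lt(abs(fa$mean - max(typicals[s], 0)), 5)
    if (typicals[s] > 10) {
      expect_lt(abs(fa$mean - typicals[s]), 2)
    }
  }
})

test_that("boundary validation flags only angles outside their state interval", {
  seg <- reference_segmentation("real")$finger_mcp_flexion
  ex <- data.frame(
    participant = c("P01", "P02", "P03"),
    primitive = "finger_mcp_flexion",
    state_index = c(2L, 3L, 3L),
    angle = c(40, 65, 70.4)
  )
  v <- validate_boundaries(ex, seg)
  expect_equal(nrow(v), 1L)
  expect_equal(v$participant, "P02")
  expect_equal(v$violated_edge, 70.4)
  expect_equal(v$margin, 5.4, tolerance = 1e-9)

  all_in <- validate_boundaries(ex[c(1, 3), ], seg)
  expect_equal(nrow(all_in), 0L)

  bad <- ex[1, ]
  bad$state_index <- 4L
  expect_error(validate_boundaries(bad, seg), "out of range")
})

test_that("boundary adjustment takes the grid point nearest the feasible midpoint", {
  expect_equal(adjust_boundary(49, 47, 65, granularity = 10), 60)
  expect_equal(adjust_boundary(32, 30, 58, granularity = 10), 50) # tie -> up
  expect_error(
    adjust_boundary(49, 47, 50, granularity = 10),
    "infeasible"
  )
  expect_error(adjust_boundary(60, 47, 55), "not below")
  # re-applying with the published output as the criterion crossing is stable
  expect_equal(adjust_boundary(49, 60, 65, granularity = 10), 60)
})

test_that("rom widening rounds the overshooting feature angle up to the grid", {
  expect_equal(widen_rom(38, 30), 40)
  expect_equal(widen_rom(25, 30), 30)
  expect_equal(widen_rom(41, 40), 50)
  expect_equal(widen_rom(30, 30), 30)
})

test_that("merging mirrored primitives keeps one neutral state and all boundaries", {
  flex <- handstates:::new_segmentation(
    "wrist_flexion", 2L, 37.2,
    rom = c(0, 80), typical_angles = c(0, 49)
  )
  ext <- handstates:::new_segmentation(
    "wrist_extension", 2L, 34.1,
    rom = c(0, 70), typical_angles = c(0, 46)
  )
  merged <- merge_pairs(flex, ext, id = "wrist_bending")
  expect_equal(merged$n_states, 3L)
  expect_equal(merged$boundaries, c(-34.1, 37.2))
  expect_equal(merged$typical_angles, c(-46, 0, 49))
  expect_equal(merged$rom, c(-70, 80))
  # boundary count preserved and strictly monotone on the signed axis
  expect_equal(length(merged$boundaries), 1L + 1L)
  expect_true(all(diff(merged$boundaries) > 0))

  one <- handstates:::new_segmentation(
    "wrist_radial_deviation", 1L, numeric(0),
    rom = c(0, 20), typical_angles = 0
  )
  two <- handstates:::new_segmentation(
    "wrist_ulnar_deviation", 2L, 11.1,
    rom = c(0, 40), typical_angles = c(0, 38)
  )
  dev <- merge_pairs(two, one, id = "wrist_deviation")
  expect_equal(dev$n_states, 2L)
  expect_equal(dev$boundaries, 11.1)
  expect_equal(dev$rom, c(-20, 40))
  expect_equal(dev$typical_angles, c(0, 38))

  both_one <- merge_pairs(one, one, id = "x")
  expect_equal(both_one$n_states, 1L)

  bad <- handstates:::new_segmentation(
    "thumb_mcp_flexion", 2L, 24.3,
    rom = c(0, 50), typical_angles = c(5, 49)
  )
  expect_error(merge_pairs(bad, one), "shared neutral")
})
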