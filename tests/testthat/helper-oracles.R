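# Independent oracles used by the tests; deliberately re-derived from first
# principles rather than calling the package's own code paths.

# Closed-form normal-equations OLS.
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - yb)^2)
  list(
    intercept = intercept, slope = slope,
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  )
}

# Shrout-Fleiss ICC(2,1) from an explicit sums-of-squares decomposition.
icc21_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Difference curve built directly from known coefficients.
curve_from_coefs <- function(intercept, slope, primitive = "toy",
                             standard_kind = "boundary_low",
                             standard_angle = 0) {
  structure(
    list(
      primitive = primitive, standard_kind = standard_kind,
      standard_angle = standard_angle,
      intercept = intercept, slope = slope,
      r_squared = 1, n_points = 2L, fit_domain = c(NA_real_, NA_real_)
    ),
    class = "difference_curve"
  )
}

# One toy primitive used across schedule tests.
toy_primitive <- function(rom_max = 10, step = 10) {
  data.frame(
    id = "toy", joint = "toy", motion_form = "flexion",
    rom_min = 0, rom_max = rom_max, contrast_step = step,
    positive_direction = "up", stringsAsFactors = FALSE
  )
}
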