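# Synthetic observers, performers and devices. These generators carry the
# statistical structure the analyses assume -- a psychometric model linear
# on the Z scale, Gaussian subject and rater noise, an affine device with
# Gaussian noise -- so every pipeline stage can be exercised end to end
# with known ground truth.

#' Synthetic observer model
#'
#' Generative counterpart of the perceptual analysis: for a standard
#' gesture s and contrast angle x, the probability of a "different"
#' judgment is `pnorm(Z(x))` with Z linear in the distance from the
#' standard, `Z(x) = baseline + slope_s * |x - s|`. The per-standard
#' slopes are derived from the model's true boundaries so that the
#' population difference curves intersect exactly at those boundaries:
#' the analysis estimand equals the generator truth by construction.
#'
#' With one true state the curves never reach the criterion; with two, the
#' boundary-curve intersection sits at the single true boundary; with
#' three, the median sits midway between the true boundaries and the
#' median-section curves cross the boundary curves at them.
#'
#' @param primitive Primitive id.
#' @param rom Length-2 aROM in degrees.
#' @param n_states True number of semantic states (1, 2 or 3).
#' @param boundaries True boundary angles (length `n_states - 1`), strictly
#'   inside the aROM.
#' @param baseline Z offset at zero distance from the standard (the
#'   within-state floor of perceived difference).
#' @param slope Discriminability of the low-boundary standard, in Z per
#'   degree; the other standards' slopes are derived from it.
#' @return An `observer_model`.
#' @export
observer_model <- function(primitive, rom, n_states, boundaries = numeric(0),
                           baseline = -1.0, slope = NULL) {
  stopifnot(length(rom) == 2L, rom[1] < rom[2], n_states %in% 1:3)
  span <- rom[2] - rom[1]
  if (n_states >= 2L) {
    stopifnot(length(boundaries) == n_states - 1L)
    if (any(boundaries <= rom[1]) || any(boundaries >= rom[2]) ||
      is.unsorted(boundaries, strictly = TRUE)) {
      stop("boundaries must be strictly increasing and inside the aROM")
    }
  }
  if (is.null(slope)) {
    # defaults placing the decision quantities on the intended side of the
    # 0.67 criterion: one state -> curve maxima at Z = 0.1; two states ->
    # Z at the boundary (the median) 0.2 with maxima well above the
    # criterion; three states -> Z at the median 1.2 while the
    # boundary-intersection Zs stay below the criterion
    slope <- switch(n_states,
      (0.1 - baseline) / span,
      (0.2 - baseline) / (boundaries[1] - rom[1]),
      (1.2 - baseline) / (mean(boundaries) - rom[1])
    )
  }
  stopifnot(slope >= 0)
  a <- rom[1]
  R <- rom[2]
  g_low <- slope
  if (n_states == 1L) {
    m <- (a + R) / 2
    g_high <- slope
    g_med_below <- g_med_above <- slope
  } else if (n_states == 2L) {
    m <- boundaries[1]
    g_high <- g_low * (m - a) / (R - m)
    g_med_below <- g_med_above <- g_low
  } else {
    m <- mean(boundaries)
    g_high <- g_low * (m - a) / (R - m)
    g_med_below <- g_low * (boundaries[1] - a) / (m - boundaries[1])
    g_med_above <- g_high * (R - boundaries[2]) / (boundaries[2] - m)
  }
  structure(
    list(
      primitive = primitive, rom = rom, n_states = as.integer(n_states),
      boundaries = boundaries, baseline = baseline, slope = slope,
      median = m,
      slopes = c(
        boundary_low = g_low, boundary_high = g_high,
        median_below = g_med_below, median_above = g_med_above
      )
    ),
    class = "observer_model"
  )
}

#' Expected Z of a synthetic observer
#'
#' @param model An `observer_model`.
#' @param standard_kind `"boundary_low"`, `"boundary_high"` or `"median"`.
#' @param contrast_angle Contrast angle(s) in degrees.
#' @return Expected average Z score(s) of the difference degree.
#' @export
observer_z <- function(model, standard_kind, contrast_angle) {
  x <- contrast_angle
  a <- model$rom[1]
  R <- model$rom[2]
  g <- model$slopes
  z0 <- model$baseline
  switch(standard_kind,
    boundary_low = z0 + g[["boundary_low"]] * (x - a),
    boundary_high = z0 + g[["boundary_high"]] * (R - x),
    median = ifelse(
      x < model$median,
      z0 + g[["median_below"]] * (model$median - x),
      z0 + g[["median_above"]] * (x - model$median)
    ),
    stop("unknown standard_kind: ", standard_kind)
  )
}

#' Simulate same/different judgments
#'
#' One Bernoulli draw per participant and schedule row, with
#' `P(different) = pnorm(observer Z)`.
#'
#' @param model An `observer_model`.
#' @param schedule Stimulus schedule from [build_exp1_schedule()] or
#'   [build_exp2_schedule()], restricted to the model's primitive.
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Judgment records suitable for [aggregate_judgments()].
#' @export
simulate_judgments <- function(model, schedule, n_participants = 20L,
                               seed = NULL) {
  schedule <- schedule[schedule$primitive == model$primitive, ]
  if (nrow(schedule) == 0L) stop("schedule contains no rows for ", model$primitive)
  p_diff <- stats::pnorm(
    unlist(lapply(seq_len(nrow(schedule)), function(i) {
      observer_z(model, schedule$standard_kind[i], schedule$contrast_angle[i])
    }))
  )
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_participants), function(pid) {
      draws <- stats::runif(nrow(schedule)) < p_diff
      data.frame(
        participant = sprintf("P%02d", pid),
        primitive = schedule$primitive,
        standard_kind = schedule$standard_kind,
        standard_angle = schedule$standard_angle,
        contrast_angle = schedule$contrast_angle,
        swap = schedule$swap,
        response = ifelse(draws, "different", "same"),
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Synthetic performer model
#'
#' Each participant's execution angle for a state is Gaussian around the
#' state's typical angle (truncated to the aROM); each rater's reading adds
#' independent Gaussian noise and is rounded to whole degrees, mirroring
#' ruler measurement.
#'
#' @param primitive Primitive id.
#' @param typical_angles Typical angle per state (degrees).
#' @param rom Length-2 aROM.
#' @param subject_sd Between-subject SD of the executed angle (degrees).
#' @param rater_sd SD of each rater's measurement noise (degrees).
#' @return A `performer_model`.
#' @export
performer_model <- function(primitive, typical_angles, rom,
                            subject_sd = 5, rater_sd = 1) {
  stopifnot(subject_sd >= 0, rater_sd >= 0, length(rom) == 2L)
  structure(
    list(
      primitive = primitive, typical_angles = typical_angles,
      rom = rom, subject_sd = subject_sd, rater_sd = rater_sd
    ),
    class = "performer_model"
  )
}

#' Simulate gesture execution records
#'
#' @param model A `performer_model`.
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return Execution records: `participant`, `primitive`,
#'   `reported_n_states`, `state_index`, `angle_rater1`, `angle_rater2`
#'   (whole degrees).
#' @export
simulate_executions <- function(model, n_participants = 20L, seed = NULL) {
  k <- length(model$typical_angles)
  with_seed(seed, {
    rows <- expand.grid(
      participant = sprintf("P%02d", seq_len(n_participants)),
      state_index = seq_len(k),
      stringsAsFactors = FALSE
    )
    true_angle <- vapply(seq_len(nrow(rows)), function(i) {
      rnorm_trunc(
        1, model$typical_angles[rows$state_index[i]], model$subject_sd,
        model$rom[1], model$rom[2]
      )
    }, numeric(1))
    read <- function() {
      round(true_angle + stats::rnorm(nrow(rows), 0, model$rater_sd))
    }
    data.frame(
      participant = rows$participant,
      primitive = model$primitive,
      reported_n_states = k,
      state_index = rows$state_index,
      angle_rater1 = read(),
      angle_rater2 = read(),
      stringsAsFactors = FALSE
    )
  })
}

#' Synthetic device model
#'
#' The device reads `intercept + slope * actual` plus Gaussian noise:
#' a per-primitive affine bias with per-reading noise (published device
#' noise SDs run up to about 12 degrees).
#'
#' @param primitive Primitive id.
#' @param intercept,slope True affine bias of the device.
#' @param noise_sd Measurement noise SD in degrees.
#' @param rom_max Maximum of the primitive's motion range (requirement
#'   angles are 0-100% of this).
#' @return A `device_model`.
#' @export
device_model <- function(primitive, intercept, slope, rom_max,
                         noise_sd = 8) {
  stopifnot(noise_sd >= 0)
  structure(
    list(
      primitive = primitive, intercept = intercept, slope = slope,
      rom_max = rom_max, noise_sd = noise_sd
    ),
    class = "device_model"
  )
}

#' Simulate device calibration records
#'
#' One measurement per subject per requirement angle (0%, 25%, 50%, 75%,
#' 100% of the motion range).
#'
#' @param model A `device_model`.
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed.
#' @return Calibration records: `participant`, `primitive`,
#'   `requirement_fraction`, `actual_angle`, `measured_angle`.
#' @export
simulate_calibration <- function(model, n_subjects = 10L, seed = NULL) {
  req <- requirement_angles(model$rom_max)
  frac <- c(0, 0.25, 0.5, 0.75, 1)
  with_seed(seed, {
    rows <- expand.grid(
      participant = sprintf("S%02d", seq_len(n_subjects)),
      idx = seq_along(req),
      stringsAsFactors = FALSE
    )
    actual <- req[rows$idx]
    measured <- model$intercept + model$slope * actual +
      stats::rnorm(nrow(rows), 0, model$noise_sd)
    data.frame(
      participant = rows$participant,
      primitive = model$primitive,
      requirement_fraction = frac[rows$idx],
      actual_angle = actual,
      measured_angle = measured,
      stringsAsFactors = FALSE
    )
  })
}
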