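#' Motion primitive units of the hand and wrist
#'
#' A motion primitive unit is one joint moving in one motion form (for
#' example, finger PIP flexion): the elementary degree of freedom from which
#' hand gestures are composed. `default_primitives()` returns the ten units
#' studied by the constant-stimuli experiments, with their active ranges of
#' motion (aROM) and the angular step between successive contrast gestures.
#'
#' @return A data frame with one row per primitive and columns
#'   `id`, `joint`, `motion_form`, `rom_min`, `rom_max` (degrees),
#'   `contrast_step` (degrees) and `positive_direction` (the sign
#'   convention of increasing angle).
#' @examples
#' p <- default_primitives()
#' nrow(p)           # 10
#' contrast_angles(p[p$id == "finger_pip_flexion", ])
#' @export
default_primitives <- function() {
  data.frame(
    id = c(
      "finger_mcp_flexion", "finger_abduction", "finger_pip_flexion",
      "thumb_mcp_flexion", "thumb_ip_flexion", "thumb_abduction",
      "wrist_flexion", "wrist_extension",
      "wrist_radial_deviation", "wrist_ulnar_deviation"
    ),
    joint = c(
      "finger MCP", "finger MCP", "finger PIP",
      "thumb MCP", "thumb IP", "thumb TMC",
      "wrist", "wrist", "wrist", "wrist"
    ),
    motion_form = c(
      "flexion", "abduction", "flexion",
      "flexion", "flexion", "abduction",
      "flexion", "extension",
      "radial_deviation", "ulnar_deviation"
    ),
    rom_min = rep(0, 10),
    rom_max = c(90, 60, 110, 50, 80, 70, 80, 70, 20, 30),
    contrast_step = c(10, 10, 10, 10, 10, 10, 10, 10, 5, 5),
    positive_direction = c(
      "toward palm", "away from middle finger", "toward palm",
      "toward palm", "toward palm", "away from palm plane",
      "palmar", "dorsal", "toward thumb", "away from thumb"
    ),
    stringsAsFactors = FALSE
  )
}

as_primitive <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    p <- as.list(p)
  }
  stopifnot(
    is.list(p),
    all(c("rom_min", "rom_max", "contrast_step") %in% names(p))
  )
  if (p$rom_min >= p$rom_max) stop("rom_min must be less than rom_max")
  if (p$contrast_step <= 0) stop("contrast_step must be positive")
  p
}

#' Contrast gesture angles of a motion primitive
#'
#' The contrast gestures of a primitive are the arithmetic sequence of
#' angles from `rom_min` to `rom_max` inclusive, spaced by `contrast_step`.
#' The step must divide the range exactly.
#'
#' @param p A single primitive: one row of [default_primitives()] or a list
#'   with `rom_min`, `rom_max` and `contrast_step`.
#' @return Numeric vector of angles in degrees.
#' @export
contrast_angles <- function(p) {
  p <- as_primitive(p)
  span <- p$rom_max - p$rom_min
  k <- span / p$contrast_step
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf(
      "contrast_step %s does not divide the range %s-%s exactly",
      p$contrast_step, p$rom_min, p$rom_max
    ))
  }
  seq(p$rom_min, p$rom_max, by = p$contrast_step)
}

make_schedule <- function(rows, seed, n_blocks) {
  empty <- data.frame(
    primitive = character(0), standard_kind = character(0),
    standard_angle = numeric(0), contrast_angle = numeric(0),
    swap = logical(0), stringsAsFactors = FALSE
  )
  sched <- do.call(rbind, c(list(empty), rows))
  rownames(sched) <- NULL
  n <- nrow(sched)
  if (n == 0L) {
    sched$block <- integer(0)
    sched$trial_index <- integer(0)
    return(sched)
  }
  perm <- with_seed(seed, sample.int(n))
  sched <- sched[perm, , drop = FALSE]
  rownames(sched) <- NULL
  # contiguous, equal-as-possible blocks after shuffling
  sched$block <- if (n_blocks <= 1L) {
    rep(1L, n)
  } else {
    as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  }
  sched$trial_index <- seq_len(n)
  sched
}

#' Build the two-boundary-standard stimulus schedule
#'
#' For every primitive, each contrast angle is paired with both boundary
#' standards (the two aROM endpoints), and each pairing appears twice: once
#' with the standard on the left and once with the positions swapped. With
#' the ten default primitives this yields 324 stimulus sets (162 unique
#' before swapping) shuffled into 3 contiguous blocks of 108 trials.
#'
#' @param primitives Data frame of primitives, as [default_primitives()].
#' @param seed Integer seed controlling the shuffle; `NULL` uses the current
#'   RNG stream.
#' @param n_blocks Number of contiguous blocks to partition the shuffled
#'   schedule into.
#' @return Data frame with columns `primitive`, `standard_kind`
#'   (`"boundary_low"`/`"boundary_high"`), `standard_angle`,
#'   `contrast_angle`, `swap`, `block`, `trial_index`.
#' @export
build_exp1_schedule <- function(primitives = default_primitives(),
                                seed = NULL, n_blocks = 3L) {
  rows <- lapply(seq_len(nrow(primitives)), function(i) {
    p <- primitives[i, ]
    ca <- contrast_angles(p)
    expand.grid(
      primitive = p$id,
      standard_kind = c("boundary_low", "boundary_high"),
      contrast_angle = ca,
      swap = c(FALSE, TRUE),
      stringsAsFactors = FALSE
    ) -> g
    g$standard_angle <- ifelse(g$standard_kind == "boundary_low",
      p$rom_min, p$rom_max
    )
    g[, c(
      "primitive", "standard_kind", "standard_angle",
      "contrast_angle", "swap"
    )]
  })
  make_schedule(rows, seed, n_blocks)
}

#' Build the median-standard stimulus schedule
#'
#' Follow-up schedule for primitives whose two-boundary analysis indicates
#' more than two semantic states: every contrast angle is paired with the
#' semantic-median standard, duplicated with the swap flag, in one block.
#'
#' @param primitives Data frame of primitives (rows of
#'   [default_primitives()]) restricted to those needing a second round.
#' @param medians Named numeric vector of semantic medians (degrees),
#'   names matching `primitives$id`.
#' @inheritParams build_exp1_schedule
#' @return Schedule data frame (see [build_exp1_schedule()]), with
#'   `standard_kind = "median"`.
#' @export
build_exp2_schedule <- function(primitives, medians, seed = NULL) {
  if (nrow(primitives) == 0L) {
    return(build_exp1_schedule(primitives[0, ], seed = NULL, n_blocks = 1L))
  }
  missing <- setdiff(primitives$id, names(medians))
  if (length(missing) > 0L) {
    stop(
      "missing median angle for primitive(s): ",
      paste(missing, collapse = ", ")
    )
  }
  rows <- lapply(seq_len(nrow(primitives)), function(i) {
    p <- primitives[i, ]
    ca <- contrast_angles(p)
    g <- expand.grid(
      primitive = p$id,
      standard_kind = "median",
      contrast_angle = ca,
      swap = c(FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    g$standard_angle <- unname(medians[[p$id]])
    g[, c(
      "primitive", "standard_kind", "standard_angle",
      "contrast_angle", "swap"
    )]
  })
  make_schedule(rows, seed, n_blocks = 1L)
}

#' Default inter-joint coupling configuration
#'
#' Sign-language research treats finger DIP flexion as following finger PIP
#' flexion, and thumb TMC flexion as following thumb MCP flexion. The
#' coupling is modeled linearly: the coupled joint's angle is
#' `coefficient * driver angle`, clamped to the coupled joint's aROM.
#'
#' @param dip_coefficient,tmc_coefficient Linear coupling coefficients.
#' @return A list of coupling rules consumed by [apply_coupling()].
#' @export
default_coupling <- function(dip_coefficient = 1.0, tmc_coefficient = 1.0) {
  list(
    finger_dip_flexion = list(
      driver = "finger_pip_flexion",
      coefficient = dip_coefficient, rom = c(0, 70)
    ),
    thumb_tmc_flexion = list(
      driver = "thumb_mcp_flexion",
      coefficient = tmc_coefficient, rom = c(0, 15)
    )
  )
}

#' Fill coupled joint angles of a pose
#'
#' @param pose Named numeric vector of primitive angles (degrees).
#' @param coupling Coupling configuration, as [default_coupling()].
#' @return The pose with one additional named angle per coupling rule whose
#'   driver is present, clamped to the coupled joint's aROM.
#' @export
apply_coupling <- function(pose, coupling = default_coupling()) {
  for (joint in names(coupling)) {
    rule <- coupling[[joint]]
    if (!rule$driver %in% names(pose)) next
    value <- rule$coefficient * pose[[rule$driver]]
    pose[[joint]] <- min(max(value, rule$rom[1]), rule$rom[2])
  }
  pose
}
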