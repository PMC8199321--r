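#' Requirement angles for device calibration
#'
#' Calibration of the hand tracker samples each primitive at 0%, 25%, 50%,
#' 75% and 100% of its maximum range of motion (all calibrated primitives
#' start at 0 degrees).
#'
#' @param p A primitive (one row of [default_primitives()] or a list with
#'   `rom_min`/`rom_max`), or a single number taken as `rom_max`.
#' @return Numeric vector of the five requirement angles in degrees.
#' @examples
#' requirement_angles(110) # 0 27.5 55 82.5 110
#' @export
requirement_angles <- function(p) {
  if (is.numeric(p) && length(p) == 1L) {
    rom_min <- 0
    rom_max <- p
  } else {
    if (is.data.frame(p)) {
      stopifnot(nrow(p) == 1L)
      p <- as.list(p)
    }
    rom_min <- p$rom_min
    rom_max <- p$rom_max
  }
  if (rom_min != 0) stop("calibrated primitives must have rom_min = 0")
  seq(0, rom_max, length.out = 5L)
}

#' Summarize device calibration records
#'
#' Per (primitive, requirement angle) cell: sample mean and standard
#' deviation of the device measurements, plus the normalized measurement
#' error `|mean measured - actual| / rom span`.
#'
#' @param records Data frame with `participant`, `primitive`,
#'   `actual_angle`, `measured_angle` and optionally
#'   `requirement_fraction`.
#' @param rom_spans Named numeric vector of motion-range spans per
#'   primitive; defaults to the span implied by the largest actual angle of
#'   each primitive (the 100% requirement).
#' @return Data frame with one row per cell: `primitive`, `actual_angle`,
#'   `n`, `mean_measured`, `sd_measured`, `normalized_error`.
#' @export
summarize_calibration <- function(records, rom_spans = NULL) {
  stop_if_missing_cols(
    records, c("primitive", "actual_angle", "measured_angle"),
    "calibration records"
  )
  if (is.null(rom_spans)) {
    rom_spans <- tapply(abs(records$actual_angle), records$primitive, max)
  }
  key <- interaction(records$primitive, records$actual_angle,
    drop = TRUE, lex.order = TRUE
  )
  out <- do.call(rbind, lapply(split(records, key), function(cell) {
    prim <- cell$primitive[1]
    data.frame(
      primitive = prim,
      actual_angle = cell$actual_angle[1],
      n = nrow(cell),
      mean_measured = mean(cell$measured_angle),
      sd_measured = if (nrow(cell) >= 2L) stats::sd(cell$measured_angle) else NA_real_,
      normalized_error = normalized_error(
        mean(cell$measured_angle), cell$actual_angle[1],
        unname(rom_spans[[prim]])
      ),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$primitive, out$actual_angle), ]
}

#' Normalized measurement error
#'
#' Motion ranges vary widely across primitives (30 to 110 degrees), so the
#' absolute deviation between the mean device measurement and the actual
#' angle is normalized by the primitive's motion-range span:
#' `|mean measured - actual| / span`.
#'
#' @param mean_measured Mean device measurement (degrees).
#' @param actual Actual (ruler-verified) angle (degrees).
#' @param rom_span Motion-range span of the primitive (degrees), positive.
#' @return Normalized error as a dimensionless fraction of the span.
#' @export
normalized_error <- function(mean_measured, actual, rom_span) {
  stopifnot(all(rom_span > 0))
  abs(mean_measured - actual) / rom_span
}

#' Fit the affine device mapping of a primitive
#'
#' Ordinary least squares of the device measurement on the actual angle.
#' For a primitive whose sign the device inverts (finger abduction is
#' reported negative while the ruler convention is positive), the
#' magnitude of the measurement is taken before fitting
#' (`sign_policy = "magnitude"`). Under a balanced design, fitting the
#' per-cell means is identical to fitting the raw records.
#'
#' @param actual,measured Numeric vectors of paired angles (degrees).
#' @param primitive Primitive id carried into the result.
#' @param sign_policy `"keep"` (default) or `"magnitude"`.
#' @return An `affine_mapping`: `intercept` (degrees), `slope`
#'   (dimensionless), `r_squared`, `n_points`.
#' @export
fit_mapping <- function(actual, measured, primitive = NA_character_,
                        sign_policy = c("keep", "magnitude")) {
  sign_policy <- match.arg(sign_policy)
  if (sign_policy == "magnitude") {
    measured <- abs(measured)
  }
  fit <- fit_line(actual, measured)
  structure(
    list(
      primitive = primitive,
      intercept = fit$intercept,
      slope = fit$slope,
      r_squared = fit$r_squared,
      n_points = fit$n,
      sign_policy = sign_policy
    ),
    class = "affine_mapping"
  )
}

#' @export
print.affine_mapping <- function(x, ...) {
  cat(sprintf(
    "Affine mapping [%s]: measured = %.2f %+.2f * actual (r2 = %.3f, n = %d)\n",
    x$primitive, x$intercept, x$slope, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Fit affine device mappings for every primitive in a calibration table
#'
#' @param records Calibration records or a cell-mean summary: a data frame
#'   with `primitive`, `actual_angle` and either `measured_angle` or
#'   `mean_measured`.
#' @param magnitude_primitives Primitive ids whose measurements are
#'   sign-inverted by the device and fitted as magnitudes.
#' @return Named list of `affine_mapping` objects.
#' @export
fit_mappings <- function(records,
                         magnitude_primitives = "finger_abduction") {
  ycol <- if ("measured_angle" %in% names(records)) {
    "measured_angle"
  } else if ("mean_measured" %in% names(records)) {
    "mean_measured"
  } else {
    stop("records need a measured_angle or mean_measured column")
  }
  prims <- unique(records$primitive)
  maps <- lapply(prims, function(id) {
    cell <- records[records$primitive == id, ]
    fit_mapping(
      cell$actual_angle, cell[[ycol]],
      primitive = id,
      sign_policy = if (id %in% magnitude_primitives) "magnitude" else "keep"
    )
  })
  names(maps) <- prims
  maps
}

#' Transfer a segmentation into device measurement space
#'
#' Applies the primitive's affine mapping to every boundary and typical
#' angle. Device output can exceed the nominal range of motion, so the
#' extreme intervals of a device-space segmentation are open-ended and no
#' clamping to the aROM is performed.
#'
#' @param seg A resolved `segmentation` in real (ruler) space.
#' @param mapping The primitive's `affine_mapping`.
#' @return A device-space `segmentation` with `open_ended = TRUE`.
#' @export
map_segmentation <- function(seg, mapping) {
  if (!is.na(mapping$primitive) && !identical(seg$primitive, mapping$primitive)) {
    stop(
      "segmentation and mapping are for different primitives: ",
      seg$primitive, " vs ", mapping$primitive
    )
  }
  map <- function(x) mapping$intercept + mapping$slope * x
  out <- new_segmentation(
    seg$primitive, seg$n_states, map(seg$boundaries),
    rom = map(seg$rom),
    typical_angles = map(seg$typical_angles),
    median_angle = if (is.na(seg$median_angle)) NA_real_ else map(seg$median_angle),
    criterion_z = seg$criterion_z,
    status = seg$status,
    provenance = c(
      seg$provenance,
      sprintf(
        "mapped to device space via measured = %.2f %+.2f * actual",
        mapping$intercept, mapping$slope
      )
    )
  )
  out$open_ended <- TRUE
  out
}

#' Invert an affine device mapping
#'
#' @param mapping An `affine_mapping` with nonzero slope.
#' @param measured Device measurement(s) in degrees.
#' @return Estimated actual angle(s): `(measured - intercept) / slope`.
#' @export
invert_mapping <- function(mapping, measured) {
  if (abs(mapping$slope) < 1e-12) {
    stop("mapping slope is zero; cannot invert")
  }
  (measured - mapping$intercept) / mapping$slope
}
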