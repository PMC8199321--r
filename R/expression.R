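#' Reconcile perceived and expressed state counts
#'
#' Gesture performers sometimes report one more state than observers
#' perceive, typically an extra state at a range-of-motion extreme driven by
#' the proprioceptive sense of exertion rather than by a visible angle
#' difference. Because such surplus states are invisible to an observer,
#' the perceptual count prevails when the modal expressed count exceeds it
#' and the surplus sits at an extreme.
#'
#' @param perception_n State count from the perceptual segmentation.
#' @param expression_counts Integer vector: each participant's reported
#'   state count.
#' @param surplus_at_extreme Logical: does the surplus expressed state sit
#'   at an aROM extreme? (`TRUE` for exertion-driven extra states.)
#' @return A list with `final_n`, the `distribution` of reported counts
#'   (a table), and `note`.
#' @export
reconcile_counts <- function(perception_n, expression_counts,
                             surplus_at_extreme = TRUE) {
  stopifnot(perception_n >= 1L)
  if (length(expression_counts) == 0L) {
    stop("expression_counts is empty")
  }
  tab <- table(expression_counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  if (modal == perception_n) {
    final <- perception_n
    note <- "expressed modal count agrees with perception"
  } else if (modal > perception_n && surplus_at_extreme) {
    final <- perception_n
    note <- paste(
      "expressed modal count exceeds perception with the surplus state at",
      "an aROM extreme; perceptual count retained (proprioceptive, not",
      "visual, difference)"
    )
  } else {
    final <- perception_n
    note <- sprintf(
      "disagreement: perception %d vs expressed modal %d; perceptual count retained, inspect distribution",
      perception_n, modal
    )
  }
  list(
    final_n = as.integer(final),
    distribution = tab,
    note = note
  )
}

#' Two-rater intraclass correlation, ICC(2,1)
#'
#' Inter-rater reliability of the two experimenters' angle measurements:
#' two-way random effects, absolute agreement, single measure
#' (Shrout-Fleiss ICC(2,1)), computed from the two-way ANOVA mean squares.
#' Measurements that are completely constant leave no variance to
#' apportion; the ICC is then undefined and reported as `NA` with a note
#' rather than an error.
#'
#' @param mat Numeric matrix, subjects in rows and the two raters in
#'   columns (at least 3 subjects).
#' @param primitive,state_index Optional labels carried into the report.
#' @return A list with `icc_value`, `n`, `k`, and `notes`.
#' @export
icc_two_rater <- function(mat, primitive = NA_character_,
                          state_index = NA_integer_) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 3L) stop("ICC needs at least 3 subjects")
  if (k != 2L) stop("icc_two_rater expects exactly 2 raters")
  if (anyNA(mat)) stop("ICC input must be complete")
  report <- function(value, notes) {
    list(
      primitive = primitive, state_index = state_index,
      icc_value = value, n = n, k = k, notes = notes
    )
  }
  if (stats::var(as.vector(mat)) == 0) {
    return(report(NA_real_, "constant data, ICC undefined"))
  }
  d <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1] # subjects
  msc <- ms[2] # raters
  mse <- ms[3] # residual
  icc <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)
  report(unname(icc), "ICC(2,1), two-way random, absolute agreement")
}

#' Feature (typical) angle of a semantic state
#'
#' The feature angle of a state is the mean execution angle after outlier
#' removal. Values (already averaged across the two raters) outside the
#' Tukey fences -- more than `k` interquartile ranges beyond the quartiles,
#' with linear-interpolation (type 7) quartiles -- are removed; the mean of
#' the survivors is reported, rounded to whole degrees for tabulation.
#'
#' @param values Numeric vector of rater-averaged execution angles.
#' @param k Fence multiplier (1.5 = standard Tukey fences).
#' @return A list with `mean` (unrounded), `reported` (rounded to 1
#'   degree), `kept` and `removed`.
#' @export
feature_angle <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values supplied")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  keep <- values >= lo & values <= hi
  if (!any(keep)) stop("all values removed as outliers")
  m <- mean(values[keep])
  list(
    mean = m,
    reported = round(m),
    kept = values[keep],
    removed = values[!keep]
  )
}

#' Check execution angles against a segmentation
#'
#' Each execution angle is checked against the interval of its reported
#' state under the lower-closed/upper-open convention (an angle exactly on
#' a boundary belongs to the upper state, so it does not violate that
#' boundary as a lower edge).
#'
#' @param executions Data frame with `participant`, `primitive`,
#'   `state_index` and `angle` (rater-averaged, degrees).
#' @param segmentation A `segmentation` for the same primitive.
#' @return Data frame of violations with the offending row, the violated
#'   edge, and the margin in degrees; zero rows when all angles fall inside
#'   their state's interval.
#' @export
validate_boundaries <- function(executions, segmentation) {
  stop_if_missing_cols(
    executions, c("participant", "primitive", "state_index", "angle"),
    "executions"
  )
  b <- segmentation$boundaries
  edges <- c(segmentation$rom[1], b, segmentation$rom[2])
  n_states <- segmentation$n_states
  out <- lapply(seq_len(nrow(executions)), function(i) {
    row <- executions[i, ]
    s <- row$state_index
    if (s < 1L || s > n_states) {
      stop(sprintf("row %d: state_index %s out of range 1..%d", i, s, n_states))
    }
    lower <- edges[s]
    upper <- edges[s + 1]
    # interior boundaries are lower-closed; the aROM edges are inclusive
    low_ok <- row$angle >= lower
    up_ok <- if (s == n_states) row$angle <= upper else row$angle < upper
    if (low_ok && up_ok) {
      return(NULL)
    }
    data.frame(
      participant = row$participant,
      primitive = row$primitive,
      state_index = s,
      angle = row$angle,
      violated_edge = if (!low_ok) lower else upper,
      margin = if (!low_ok) lower - row$angle else row$angle - upper,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      participant = character(0), primitive = character(0),
      state_index = integer(0), angle = numeric(0),
      violated_edge = numeric(0), margin = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Adjust a state boundary between execution and perception constraints
#'
#' When executions of the upper state dip below the perceptual boundary,
#' the demarcation line is re-set inside the feasible window: it must
#' strictly exceed the maximum execution angle of the lower state, reach at
#' least the angle where the difference curve crosses the Z criterion, and
#' stay strictly below the minimum execution angle of the upper state. The new
#' boundary is the multiple of `granularity` nearest the midpoint of that
#' window (ties rounded up), leaving redundancy on both sides.
#'
#' @param lower_state_max Maximum execution angle of the lower state
#'   (degrees).
#' @param z_crossing Angle where the relevant difference curve crosses the
#'   criterion (degrees).
#' @param upper_state_min Minimum execution angle of the upper state
#'   (degrees).
#' @param granularity Rounding grid in degrees.
#' @return The adjusted boundary in degrees.
#' @examples
#' adjust_boundary(49, 47, 65) # 60
#' @export
adjust_boundary <- function(lower_state_max, z_crossing, upper_state_min,
                            granularity = 10) {
  stopifnot(granularity > 0)
  lower <- max(lower_state_max, z_crossing)
  if (lower >= upper_state_min) {
    stop(sprintf(
      "infeasible constraints: lower bound %g is not below upper bound %g",
      lower, upper_state_min
    ))
  }
  mid <- (lower + upper_state_min) / 2
  lo_mult <- floor(mid / granularity) * granularity
  hi_mult <- lo_mult + granularity
  cand <- if (mid - lo_mult < hi_mult - mid) lo_mult else hi_mult
  # strictly above the lower state's maximum execution (avoids execution
  # ambiguity), at or above the criterion crossing (the crossing angle
  # itself already separates the regions), strictly below the upper
  # state's minimum
  feasible <- function(x) {
    x > lower_state_max && x >= z_crossing && x < upper_state_min
  }
  if (!feasible(cand)) {
    # fall back to any feasible multiple, preferring proximity to the
    # midpoint (ties up)
    mults <- seq(
      ceiling(lower / granularity) * granularity,
      floor(upper_state_min / granularity) * granularity,
      by = granularity
    )
    mults <- mults[vapply(mults, feasible, logical(1))]
    if (length(mults) == 0L) {
      stop(sprintf(
        "infeasible constraints: no multiple of %g strictly inside (%g, %g)",
        granularity, lower, upper_state_min
      ))
    }
    d <- abs(mults - mid)
    cand <- max(mults[d == min(d)])
  }
  cand
}

#' Widen a range of motion to cover a measured feature angle
#'
#' Published aROM limits are conservative so that most healthy people can
#' reach them; a measured state feature angle can exceed the nominal
#' maximum. When it does, the maximum is widened to the next multiple of
#' `granularity` at or above the feature angle.
#'
#' @param feature_angle Measured feature angle in degrees.
#' @param rom_max Nominal aROM maximum in degrees.
#' @param granularity Rounding grid in degrees.
#' @return The (possibly widened) aROM maximum.
#' @examples
#' widen_rom(38, 30) # 40
#' @export
widen_rom <- function(feature_angle, rom_max, granularity = 10) {
  stopifnot(granularity > 0)
  if (feature_angle <= rom_max) {
    return(rom_max)
  }
  ceiling(feature_angle / granularity) * granularity
}

#' Merge two opposite-direction primitives into one signed axis
#'
#' Primitives that are the two directions of the same joint plane (wrist
#' flexion/extension, radial/ulnar deviation) share their neutral first
#' state at 0 degrees. They merge into one signed axis: `seg_pos` keeps its
#' sign, `seg_neg` is mirrored to negative angles, and the shared neutral
#' state is counted once, so the merged state count is
#' `n_pos + n_neg - 1`.
#'
#' @param seg_pos `segmentation` of the positive-direction primitive.
#' @param seg_neg `segmentation` of the mirrored (negative) primitive.
#' @param id Id for the merged primitive.
#' @return A merged `segmentation` on the signed axis, with typical angles
#'   merged when both inputs carry them.
#' @export
merge_pairs <- function(seg_pos, seg_neg, id = NULL) {
  t_pos <- seg_pos$typical_angles[1]
  t_neg <- seg_neg$typical_angles[1]
  if (!isTRUE(all.equal(t_pos, 0)) || !isTRUE(all.equal(t_neg, 0))) {
    stop("first-state typical angles must both be 0 (shared neutral state)")
  }
  boundaries <- c(-rev(seg_neg$boundaries), seg_pos$boundaries)
  typical <- c(
    -rev(seg_neg$typical_angles[-1]),
    seg_pos$typical_angles
  )
  n <- seg_pos$n_states + seg_neg$n_states - 1L
  new_segmentation(
    id %||% paste(seg_pos$primitive, seg_neg$primitive, sep = "+"),
    n, boundaries,
    rom = c(-seg_neg$rom[2], seg_pos$rom[2]),
    typical_angles = typical,
    criterion_z = seg_pos$criterion_z,
    provenance = sprintf(
      "merged %s (positive) with mirrored %s (negative); shared neutral state",
      seg_pos$primitive, seg_neg$primitive
    )
  )
}
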