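#' Just-noticeable-difference criterion on the Z scale
#'
#' The constant-stimuli convention takes a contrast stimulus as noticeably
#' different from the standard when at least 75% of trials are judged
#' different; on the probit scale that is `qnorm(0.75)` = 0.6745, reported
#' as 0.67. Threshold comparisons use the full-precision value.
#'
#' @return The criterion Z value.
#' @export
z_criterion <- function() stats::qnorm(0.75)

#' Probit transform of a difference degree
#'
#' Converts the proportion of "different" judgments (the difference degree)
#' to the average Z score, i.e. the standard-normal quantile. Proportions of
#' exactly 0 or 1 are extreme values that the analysis excludes: they map to
#' `NA` rather than +/-Inf.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Z scores; `NA` where `p` is 0 or 1.
#' @examples
#' proportion_to_z(0.75) # 0.6745
#' @export
proportion_to_z <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  z <- stats::qnorm(p)
  z[p %in% c(0, 1)] <- NA_real_
  z
}

#' @rdname proportion_to_z
#' @param z Numeric vector of Z scores.
#' @export
z_to_proportion <- function(z) stats::pnorm(z)

#' Aggregate same/different judgments into difference points
#'
#' Judgments are pooled across participants and across the two swapped
#' presentations of each stimulus pair before computing the difference
#' degree (proportion judged "different") per
#' `(primitive, standard, contrast angle)` cell.
#'
#' @param judgments Data frame with columns `participant`, `primitive`,
#'   `standard_kind`, `standard_angle`, `contrast_angle`, `swap`,
#'   `response` (`"same"`/`"different"`).
#' @param correction If `TRUE`, apply the 1/(2n) continuity correction to
#'   proportions of exactly 0 or 1 instead of excluding them. Off by
#'   default: the canonical analysis drops extreme cells.
#' @return Data frame of difference points: one row per cell with
#'   `n_total`, `n_different`, `proportion` and `z` (`NA` when the
#'   proportion is extreme and no correction is applied).
#' @export
aggregate_judgments <- function(judgments, correction = FALSE) {
  stop_if_missing_cols(judgments, c(
    "participant", "primitive", "standard_kind", "standard_angle",
    "contrast_angle", "swap", "response"
  ), "judgments")
  bad <- setdiff(unique(judgments$response), c("same", "different"))
  if (length(bad) > 0L) {
    stop("response must be 'same' or 'different'; found: ",
      paste(bad, collapse = ", "))
  }
  key <- interaction(
    judgments$primitive, judgments$standard_kind,
    judgments$standard_angle, judgments$contrast_angle,
    drop = TRUE, lex.order = TRUE
  )
  agg <- do.call(rbind, lapply(split(judgments, key), function(cell) {
    data.frame(
      primitive = cell$primitive[1],
      standard_kind = cell$standard_kind[1],
      standard_angle = cell$standard_angle[1],
      contrast_angle = cell$contrast_angle[1],
      n_total = nrow(cell),
      n_different = sum(cell$response == "different"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$primitive, agg$standard_kind, agg$contrast_angle), ]
  agg$proportion <- agg$n_different / agg$n_total
  if (correction) {
    p <- agg$proportion
    p[p == 0] <- 1 / (2 * agg$n_total[p == 0])
    p[p == 1] <- 1 - 1 / (2 * agg$n_total[p == 1])
    agg$z <- stats::qnorm(p)
  } else {
    agg$z <- proportion_to_z(agg$proportion)
  }
  rownames(agg) <- NULL
  agg
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors of equal length with at least two distinct
#'   `x` values.
#' @return A list with `intercept`, `slope`, `r_squared` and `n`.
#' @export
fit_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("fit_line needs at least two distinct finite x values")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    n = length(x)
  )
}

#' Fit a difference-perception curve for one standard gesture
#'
#' Fits the average Z score against contrast angle by ordinary least
#' squares, after dropping cells whose difference degree was 0 or 1
#' (`z = NA`).
#'
#' @param points Difference points from [aggregate_judgments()] restricted
#'   to one `(primitive, standard)` cell, or any data frame with
#'   `contrast_angle` and `z`.
#' @param primitive,standard_kind,standard_angle Curve identity; taken from
#'   `points` when present.
#' @return A `difference_curve` object: intercept and slope on the Z scale
#'   (Z per degree), `r_squared`, `n_points`, and the angle `fit_domain`.
#' @export
fit_difference_curve <- function(points, primitive = NULL,
                                 standard_kind = NULL,
                                 standard_angle = NULL) {
  stop_if_missing_cols(points, c("contrast_angle", "z"), "difference points")
  primitive <- primitive %||% points$primitive[1]
  standard_kind <- standard_kind %||% points$standard_kind[1]
  standard_angle <- standard_angle %||% points$standard_angle[1]
  keep <- is.finite(points$z)
  pts <- points[keep, ]
  fit <- fit_line(pts$contrast_angle, pts$z)
  structure(
    list(
      primitive = primitive,
      standard_kind = standard_kind,
      standard_angle = standard_angle,
      intercept = fit$intercept,
      slope = fit$slope,
      r_squared = fit$r_squared,
      n_points = fit$n,
      fit_domain = range(pts$contrast_angle)
    ),
    class = "difference_curve"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.difference_curve <- function(x, ...) {
  cat(sprintf(
    "Difference curve [%s | %s @ %g deg]: Z = %.4f %+.4f * angle (r2 = %.3f, n = %d)\n",
    x$primitive %||% "?", x$standard_kind %||% "?", x$standard_angle %||% NA,
    x$intercept, x$slope, x$r_squared, x$n_points
  ))
  invisible(x)
}

curve_eval <- function(curve, angle) curve$intercept + curve$slope * angle

#' Intersection of two difference curves
#'
#' At the intersection the contrast angle carries the same average Z score
#' relative to both standards; for the two boundary-standard curves this
#' angle is the semantic median of the primitive.
#'
#' @param c1,c2 `difference_curve` objects for the same primitive.
#' @return A list with `angle` and `z` at the intersection.
#' @export
intersect_curves <- function(c1, c2) {
  if (!is.null(c1$primitive) && !is.null(c2$primitive) &&
    !identical(c1$primitive, c2$primitive)) {
    stop("curves belong to different primitives: ",
      c1$primitive, " vs ", c2$primitive)
  }
  db <- c1$slope - c2$slope
  if (abs(db) < 1e-12) {
    stop("curves are parallel; no unique intersection")
  }
  angle <- (c2$intercept - c1$intercept) / db
  list(angle = angle, z = curve_eval(c1, angle))
}

#' Maximum of a fitted difference curve over the range of motion
#'
#' The fitted lines increase away from their standard gesture, so the
#' curve's maximum over the aROM is its fitted value at the endpoint
#' opposite the standard: the high endpoint for a low-boundary (or
#' below-median) standard, the low endpoint otherwise. Extrapolation beyond
#' the aROM is never performed.
#'
#' @param curve A `difference_curve`.
#' @param rom Length-2 numeric, the primitive's `(rom_min, rom_max)`.
#' @return Fitted Z at the relevant aROM endpoint.
#' @export
curve_max <- function(curve, rom) {
  stopifnot(length(rom) == 2L, rom[1] < rom[2])
  at <- switch(curve$standard_kind %||% "boundary_low",
    boundary_low = rom[2],
    median_below = rom[1],
    median_above = rom[2],
    boundary_high = rom[1],
    # unknown standard: fall back on the slope direction
    if (curve$slope >= 0) rom[2] else rom[1]
  )
  curve_eval(curve, at)
}

new_segmentation <- function(primitive, n_states, boundaries, rom,
                             typical_angles = rep(NA_real_, n_states),
                             median_angle = NA_real_,
                             criterion_z = z_criterion(),
                             status = "resolved",
                             provenance = character()) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) > 0L) {
    if (any(diff(boundaries) <= 0)) {
      stop("segmentation boundaries must be strictly increasing")
    }
  }
  if (status == "resolved" && n_states != length(boundaries) + 1L) {
    stop("n_states must equal length(boundaries) + 1")
  }
  structure(
    list(
      primitive = primitive,
      n_states = as.integer(n_states),
      boundaries = boundaries,
      typical_angles = typical_angles,
      median_angle = median_angle,
      criterion_z = criterion_z,
      rom = as.numeric(rom),
      status = status,
      provenance = provenance
    ),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "Segmentation [%s]: %d state(s), boundaries {%s}, rom [%g, %g] (%s)\n",
    x$primitive, x$n_states,
    paste(signif(x$boundaries, 4), collapse = ", "),
    x$rom[1], x$rom[2], x$status
  ))
  invisible(x)
}

#' First-round semantic state segmentation from boundary-standard curves
#'
#' Decision rule applied to the two boundary-standard difference curves of a
#' primitive: (i) if both curve maxima fall below the criterion, the two
#' boundary gestures are not perceived as different and the primitive
#' carries a single semantic state; (ii) if the maxima reach the criterion
#' but the Z at the semantic median does not, the primitive carries two
#' states split at the median; (iii) if the Z at the median also reaches the
#' criterion, more than two states are present and a second,
#' median-standard round is required ([segment_round2()]).
#'
#' @param curve_low,curve_high `difference_curve` objects fitted to the
#'   low- and high-boundary standards of one primitive.
#' @param rom Length-2 numeric aROM of the primitive.
#' @param criterion Z criterion; defaults to [z_criterion()].
#' @return A `segmentation` whose `status` is `"resolved"`,
#'   `"round2_required"`, or `"unresolvable"` (median outside the aROM;
#'   clamping is deliberately not performed).
#' @export
segment_round1 <- function(curve_low, curve_high, rom,
                           criterion = z_criterion()) {
  stopifnot(identical(curve_low$primitive, curve_high$primitive))
  primitive <- curve_low$primitive
  max_low <- curve_max(curve_low, rom)
  max_high <- curve_max(curve_high, rom)
  if (max_low < criterion && max_high < criterion) {
    return(new_segmentation(
      primitive, 1L, numeric(0), rom,
      criterion_z = criterion,
      provenance = sprintf(
        "both curve maxima (%.3f, %.3f) below criterion %.4f",
        max_low, max_high, criterion
      )
    ))
  }
  med <- intersect_curves(curve_low, curve_high)
  if (med$angle <= rom[1] || med$angle >= rom[2]) {
    return(new_segmentation(
      primitive, 0L, numeric(0), rom,
      criterion_z = criterion, status = "unresolvable",
      provenance = sprintf(
        "semantic median %.2f falls outside the aROM [%g, %g]",
        med$angle, rom[1], rom[2]
      )
    ))
  }
  if (med$z < criterion) {
    new_segmentation(
      primitive, 2L, med$angle, rom,
      median_angle = med$angle, criterion_z = criterion,
      provenance = sprintf(
        "two states split at semantic median %.2f (Z = %.3f < %.4f)",
        med$angle, med$z, criterion
      )
    )
  } else {
    new_segmentation(
      primitive, 3L, numeric(0), rom,
      median_angle = med$angle, criterion_z = criterion,
      status = "round2_required",
      provenance = sprintf(
        "Z at semantic median %.2f is %.3f >= %.4f: more than two states",
        med$angle, med$z, criterion
      )
    )
  }
}

#' Second-round segmentation using median-standard curves
#'
#' For primitives flagged by [segment_round1()], the median-standard
#' judgments are fitted in two sections (contrast angles strictly below
#' and strictly above the semantic median). If both section maxima reach
#' the criterion, the primitive carries three states, bounded by the
#' intersection of the below-median section with the low-boundary curve
#' and of the above-median section with the high-boundary curve. Each
#' intersection's Z must stay below the criterion (region homogeneity);
#' otherwise the segmentation is flagged as needing a deeper split,
#' which this analysis does not perform.
#'
#' @param seg1 `segmentation` from [segment_round1()] with status
#'   `"round2_required"`.
#' @param curve_low,curve_high The boundary-standard curves.
#' @param curve_med_below,curve_med_above The two median-standard curve
#'   sections (`standard_kind` `"median_below"`/`"median_above"`).
#' @inheritParams segment_round1
#' @return A resolved three-state `segmentation`, or one flagged
#'   `"unresolvable"`/`"needs_deeper_split"` with diagnostics in
#'   `provenance`.
#' @export
segment_round2 <- function(seg1, curve_low, curve_high,
                           curve_med_below, curve_med_above,
                           rom = seg1$rom, criterion = seg1$criterion_z) {
  if (!identical(seg1$status, "round2_required")) {
    stop("segment_round2 applies only to segmentations flagged 'round2_required'")
  }
  max_below <- curve_max(curve_med_below, rom)
  max_above <- curve_max(curve_med_above, rom)
  if (max_below < criterion || max_above < criterion) {
    return(new_segmentation(
      seg1$primitive, 2L, seg1$median_angle, rom,
      median_angle = seg1$median_angle, criterion_z = criterion,
      provenance = sprintf(
        "median-curve maxima (%.3f, %.3f) do not both reach %.4f; two states retained",
        max_below, max_above, criterion
      )
    ))
  }
  b1 <- intersect_curves(curve_med_below, curve_low)
  b2 <- intersect_curves(curve_med_above, curve_high)
  if (b1$angle <= rom[1] || b2$angle >= rom[2] || b1$angle >= b2$angle) {
    return(new_segmentation(
      seg1$primitive, 0L, numeric(0), rom,
      median_angle = seg1$median_angle, criterion_z = criterion,
      status = "unresolvable",
      provenance = sprintf(
        "intersections %.2f / %.2f not ordered inside the aROM [%g, %g]",
        b1$angle, b2$angle, rom[1], rom[2]
      )
    ))
  }
  status <- "resolved"
  notes <- sprintf(
    "three states; boundaries at curve intersections %.2f (Z = %.3f) and %.2f (Z = %.3f)",
    b1$angle, b1$z, b2$angle, b2$z
  )
  if (b1$z >= criterion || b2$z >= criterion) {
    status <- "needs_deeper_split"
    notes <- paste(
      notes,
      "- intersection Z reaches the criterion: regions not homogeneous"
    )
  }
  new_segmentation(
    seg1$primitive, 3L, c(b1$angle, b2$angle), rom,
    median_angle = seg1$median_angle, criterion_z = criterion,
    status = status, provenance = notes
  )
}

#' Segment one primitive from raw judgment records
#'
#' Convenience wrapper running the full perceptual analysis for one
#' primitive: aggregate judgments, fit the boundary-standard curves, apply
#' the first-round decision rule, and, when a second round is required and
#' median-standard judgments are supplied, fit the two median sections and
#' apply the second-round rule. The median-standard data are split strictly
#' below / strictly above the median angle; a cell at the median itself is
#' excluded.
#'
#' @param judgments_exp1 Judgment records with boundary standards.
#' @param judgments_exp2 Optional judgment records with the median standard.
#' @param primitive Primitive id to analyse.
#' @param rom Length-2 aROM; defaults to the primitive's entry in
#'   [default_primitives()].
#' @inheritParams segment_round1
#' @return A `segmentation`.
#' @export
segment_primitive <- function(judgments_exp1, judgments_exp2 = NULL,
                              primitive, rom = NULL,
                              criterion = z_criterion()) {
  if (is.null(rom)) {
    prim <- default_primitives()
    row <- prim[prim$id == primitive, ]
    if (nrow(row) != 1L) stop("unknown primitive and no rom supplied: ", primitive)
    rom <- c(row$rom_min, row$rom_max)
  }
  pts <- aggregate_judgments(
    judgments_exp1[judgments_exp1$primitive == primitive, ]
  )
  curve_low <- fit_difference_curve(pts[pts$standard_kind == "boundary_low", ])
  curve_high <- fit_difference_curve(pts[pts$standard_kind == "boundary_high", ])
  seg1 <- segment_round1(curve_low, curve_high, rom, criterion)
  if (!identical(seg1$status, "round2_required") || is.null(judgments_exp2)) {
    return(seg1)
  }
  pts2 <- aggregate_judgments(
    judgments_exp2[judgments_exp2$primitive == primitive, ]
  )
  m <- seg1$median_angle
  below <- pts2[pts2$contrast_angle < m, ]
  above <- pts2[pts2$contrast_angle > m, ]
  cb <- fit_difference_curve(below, standard_kind = "median_below")
  ca <- fit_difference_curve(above, standard_kind = "median_above")
  segment_round2(seg1, curve_low, curve_high, cb, ca, rom, criterion)
}
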