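# CSV and JSON serialization shared by all modules, plus the end-to-end
# pipeline driver. All files are UTF-8; angles are decimal degrees.

judgment_cols <- c(
  "participant", "primitive", "standard_kind", "standard_angle",
  "contrast_angle", "swap", "response"
)
execution_cols <- c(
  "participant", "primitive", "reported_n_states", "state_index",
  "angle_rater1", "angle_rater2"
)
calibration_cols <- c(
  "participant", "primitive", "requirement_fraction", "actual_angle",
  "measured_angle"
)
schedule_cols <- c(
  "primitive", "standard_kind", "standard_angle", "contrast_angle",
  "swap", "block", "trial_index"
)

read_schema_csv <- function(path, cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stop_if_missing_cols(df, cols, sprintf("%s file '%s'", what, path))
  df[, cols]
}

#' Read and write the tabular record schemas
#'
#' Strict CSV readers and writers for the four record schemas: judgments
#' (`participant, primitive, standard_kind, standard_angle,
#' contrast_angle, swap, response`), executions (`participant, primitive,
#' reported_n_states, state_index, angle_rater1, angle_rater2`),
#' calibrations (`participant, primitive, requirement_fraction,
#' actual_angle, measured_angle`) and stimulus schedules. Readers fail
#' with the missing column names; writers emit plain UTF-8 CSV.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return Readers return the validated data frame (columns in schema
#'   order); writers return `path` invisibly.
#' @name record_io
NULL

#' @rdname record_io
#' @export
read_judgments_csv <- function(path) {
  df <- read_schema_csv(path, judgment_cols, "judgments")
  bad <- setdiff(unique(df$response), c("same", "different"))
  if (length(bad) > 0L) {
    stop("invalid response value(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  df$swap <- as.logical(df$swap)
  df
}

#' @rdname record_io
#' @export
write_judgments_csv <- function(x, path) {
  stop_if_missing_cols(x, judgment_cols, "judgments")
  utils::write.csv(x[, judgment_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
read_executions_csv <- function(path) {
  read_schema_csv(path, execution_cols, "executions")
}

#' @rdname record_io
#' @export
write_executions_csv <- function(x, path) {
  stop_if_missing_cols(x, execution_cols, "executions")
  utils::write.csv(x[, execution_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
read_calibration_csv <- function(path) {
  read_schema_csv(path, calibration_cols, "calibration")
}

#' @rdname record_io
#' @export
write_calibration_csv <- function(x, path) {
  stop_if_missing_cols(x, calibration_cols, "calibration")
  utils::write.csv(x[, calibration_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
read_schedule_csv <- function(path) {
  df <- read_schema_csv(path, schedule_cols, "schedule")
  df$swap <- as.logical(df$swap)
  df
}

#' @rdname record_io
#' @export
write_schedule_csv <- function(x, path) {
  stop_if_missing_cols(x, schedule_cols, "schedule")
  utils::write.csv(x[, schedule_cols], path, row.names = FALSE)
  invisible(path)
}

#' Serialize segmentations to and from JSON
#'
#' A segmentation is stored as an object with `primitive`, `n_states`,
#' `boundaries`, `typical_angles`, `median_angle`, `criterion_z`, `rom`,
#' `status`, `open_ended` and `provenance`. Reading validates the
#' invariants (strictly increasing boundaries inside the range,
#' `n_states = length(boundaries) + 1` for resolved segmentations).
#'
#' @param segs A `segmentation` or named list of them.
#' @param path File path.
#' @return `write_segmentation_json()` returns `path` invisibly;
#'   `read_segmentation_json()` returns a named list of `segmentation`
#'   objects.
#' @export
write_segmentation_json <- function(segs, path) {
  if (inherits(segs, "segmentation")) {
    segs <- stats::setNames(list(segs), segs$primitive)
  }
  payload <- lapply(segs, function(s) {
    list(
      primitive = s$primitive,
      n_states = s$n_states,
      boundaries = s$boundaries,
      typical_angles = s$typical_angles,
      median_angle = s$median_angle,
      criterion_z = s$criterion_z,
      rom = s$rom,
      status = s$status,
      open_ended = isTRUE(s$open_ended),
      provenance = s$provenance
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_segmentation_json
#' @export
read_segmentation_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  as_num <- function(v) {
    if (is.null(v)) {
      return(numeric(0))
    }
    if (is.list(v)) {
      return(vapply(
        v, function(el) if (is.null(el)) NA_real_ else as.numeric(el),
        numeric(1)
      ))
    }
    as.numeric(v)
  }
  out <- lapply(raw, function(s) {
    seg <- new_segmentation(
      s$primitive, s$n_states, as_num(s$boundaries),
      rom = as_num(s$rom),
      typical_angles = as_num(s$typical_angles),
      median_angle = if (is.null(s$median_angle)) NA_real_ else s$median_angle,
      criterion_z = s$criterion_z,
      status = s$status,
      provenance = as.character(unlist(s$provenance))
    )
    seg$open_ended <- isTRUE(s$open_ended)
    seg
  })
  names(out) <- vapply(out, function(s) s$primitive, character(1))
  out
}

#' Run the full segmentation-and-calibration pipeline
#'
#' Executes the analysis end to end: perceptual segmentation per primitive
#' (two-boundary round, then the median round where required), expression
#' checks (inter-rater ICC per state, feature angles with outlier removal,
#' boundary validation), device calibration (affine mapping per
#' primitive), and transfer of every resolved segmentation into device
#' space. When `out_dir` is given, the artifacts are written there as
#' JSON/CSV files.
#'
#' @param judgments_exp1 Boundary-standard judgment records.
#' @param judgments_exp2 Median-standard judgment records, or `NULL`.
#' @param executions Execution records, or `NULL` to skip expression
#'   checks.
#' @param calibration Calibration records, or `NULL` to skip device
#'   mapping.
#' @param primitives Primitive definitions (id, rom) to analyse; defaults
#'   to those present in `judgments_exp1`.
#' @param criterion Z criterion for segmentation.
#' @param out_dir Optional output directory.
#' @return A list with `segmentations` (real space), `reliability`,
#'   `feature_angles`, `violations`, `mappings` and
#'   `device_segmentations`.
#' @export
run_pipeline <- function(judgments_exp1, judgments_exp2 = NULL,
                         executions = NULL, calibration = NULL,
                         primitives = NULL, criterion = z_criterion(),
                         out_dir = NULL) {
  stop_if_missing_cols(judgments_exp1, judgment_cols, "judgments_exp1")
  if (is.null(primitives)) {
    all_prim <- default_primitives()
    ids <- unique(judgments_exp1$primitive)
    unknown <- setdiff(ids, all_prim$id)
    if (length(unknown) > 0L) {
      stop(
        "judgments reference unknown primitive id(s): ",
        paste(unknown, collapse = ", ")
      )
    }
    primitives <- all_prim[all_prim$id %in% ids, ]
  }

  segs <- lapply(seq_len(nrow(primitives)), function(i) {
    p <- primitives[i, ]
    segment_primitive(
      judgments_exp1, judgments_exp2,
      primitive = p$id, rom = c(p$rom_min, p$rom_max),
      criterion = criterion
    )
  })
  names(segs) <- primitives$id

  reliability <- NULL
  features <- NULL
  violations <- NULL
  if (!is.null(executions)) {
    stop_if_missing_cols(executions, execution_cols, "executions")
    key <- interaction(executions$primitive, executions$state_index,
      drop = TRUE, lex.order = TRUE
    )
    rel_rows <- lapply(split(executions, key), function(cell) {
      rep <- tryCatch(
        icc_two_rater(
          cbind(cell$angle_rater1, cell$angle_rater2),
          primitive = cell$primitive[1],
          state_index = cell$state_index[1]
        ),
        error = function(e) {
          list(
            primitive = cell$primitive[1],
            state_index = cell$state_index[1],
            icc_value = NA_real_, n = nrow(cell), k = 2L,
            notes = conditionMessage(e)
          )
        }
      )
      data.frame(
        primitive = rep$primitive, state_index = rep$state_index,
        icc_value = rep$icc_value, n = rep$n, notes = rep$notes,
        stringsAsFactors = FALSE
      )
    })
    reliability <- do.call(rbind, rel_rows)
    rownames(reliability) <- NULL

    executions$angle <- (executions$angle_rater1 + executions$angle_rater2) / 2
    feat_rows <- lapply(split(executions, key), function(cell) {
      fa <- feature_angle(cell$angle)
      data.frame(
        primitive = cell$primitive[1], state_index = cell$state_index[1],
        feature_angle = fa$reported, n_kept = length(fa$kept),
        n_removed = length(fa$removed), stringsAsFactors = FALSE
      )
    })
    features <- do.call(rbind, feat_rows)
    rownames(features) <- NULL

    viol_rows <- lapply(names(segs), function(id) {
      seg <- segs[[id]]
      if (!identical(seg$status, "resolved")) {
        return(NULL)
      }
      ex <- executions[executions$primitive == id &
        executions$reported_n_states == seg$n_states, ]
      if (nrow(ex) == 0L) {
        return(NULL)
      }
      validate_boundaries(ex, seg)
    })
    violations <- do.call(rbind, viol_rows)
  }

  mappings <- NULL
  device_segs <- NULL
  if (!is.null(calibration)) {
    stop_if_missing_cols(calibration, calibration_cols, "calibration")
    mappings <- fit_mappings(calibration)
    device_segs <- lapply(names(segs), function(id) {
      seg <- segs[[id]]
      if (!identical(seg$status, "resolved") || is.null(mappings[[id]])) {
        return(NULL)
      }
      map_segmentation(seg, mappings[[id]])
    })
    names(device_segs) <- names(segs)
    device_segs <- Filter(Negate(is.null), device_segs)
  }

  result <- list(
    segmentations = segs,
    reliability = reliability,
    feature_angles = features,
    violations = violations,
    mappings = mappings,
    device_segmentations = device_segs
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_segmentation_json(segs, file.path(out_dir, "segmentations.json"))
    if (!is.null(device_segs) && length(device_segs) > 0L) {
      write_segmentation_json(
        device_segs, file.path(out_dir, "segmentations_device.json")
      )
    }
    if (!is.null(reliability)) {
      utils::write.csv(reliability, file.path(out_dir, "reliability.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(features)) {
      utils::write.csv(features, file.path(out_dir, "feature_angles.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(violations)) {
      utils::write.csv(violations, file.path(out_dir, "violations.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(mappings)) {
      jsonlite::write_json(
        lapply(mappings, function(m) {
          list(
            primitive = m$primitive, intercept = m$intercept,
            slope = m$slope, r_squared = m$r_squared, n_points = m$n_points
          )
        }),
        file.path(out_dir, "mappings.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  result
}
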