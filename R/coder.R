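#' Encode a hand pose as a discrete semantic code
#'
#' Assigns each primitive angle of a pose to its semantic state under the
#' lower-closed/upper-open interval convention: an angle below the first
#' boundary is state 1, an angle at or above the last boundary is the top
#' state. In real space, angles outside the (widened) range of motion are
#' clamped and flagged; in device space (`open_ended` segmentations) no
#' clamping is ever applied, because device output can exceed the nominal
#' range.
#'
#' @param pose Named numeric vector: one angle in degrees per primitive.
#' @param segs Named list of resolved `segmentation` objects, as
#'   [reference_segmentation()].
#' @return A `semantic_code`: data frame with `primitive`, `state_index`
#'   and `out_of_range`.
#' @examples
#' segs <- reference_segmentation("real")
#' encode_pose(c(finger_pip_flexion = 91), segs)$state_index # 3
#' @export
encode_pose <- function(pose, segs) {
  unknown <- setdiff(names(pose), names(segs))
  if (length(unknown) > 0L) {
    stop("no segmentation for primitive(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(pose), function(id) {
    seg <- segs[[id]]
    if (!identical(seg$status, "resolved")) {
      stop("segmentation for ", id, " is not resolved: ", seg$status)
    }
    angle <- pose[[id]]
    open_ended <- isTRUE(seg$open_ended)
    oor <- FALSE
    if (!open_ended) {
      oor <- angle < seg$rom[1] || angle > seg$rom[2]
      angle <- min(max(angle, seg$rom[1]), seg$rom[2])
    }
    state <- findInterval(angle, seg$boundaries) + 1L
    data.frame(
      primitive = id, state_index = state, out_of_range = oor,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("semantic_code", class(out))
  out
}

#' Decode a semantic code into a pose of typical angles
#'
#' Replaces each state index by the typical (feature) angle of that state,
#' producing the representative pose of the code; suitable for driving a
#' virtual hand model.
#'
#' @param code A `semantic_code` (or data frame with `primitive` and
#'   `state_index`).
#' @param segs Named list of resolved `segmentation` objects carrying
#'   typical angles.
#' @return Named numeric vector of typical angles in degrees.
#' @export
decode_code <- function(code, segs) {
  stop_if_missing_cols(code, c("primitive", "state_index"), "semantic code")
  angles <- vapply(seq_len(nrow(code)), function(i) {
    id <- code$primitive[i]
    seg <- segs[[id]]
    if (is.null(seg)) stop("no segmentation for primitive: ", id)
    s <- code$state_index[i]
    if (s < 1L || s > seg$n_states) {
      stop(sprintf(
        "invalid state index %s for %s (1..%d)", s, id, seg$n_states
      ))
    }
    seg$typical_angles[s]
  }, numeric(1))
  names(angles) <- code$primitive
  angles
}

#' Size of the discrete code space
#'
#' @param segs Named list of `segmentation` objects.
#' @return The number of distinct semantic codes, i.e. the product of the
#'   state counts.
#' @export
code_space_size <- function(segs) {
  prod(vapply(segs, function(s) as.numeric(s$n_states), numeric(1)))
}
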