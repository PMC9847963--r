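#' One timepoint's automated detector output
#'
#' A `volume_annotation` holds, for a single participant-timepoint, the
#' per-slice bounding boxes the detector placed around the left and right
#' arytenoid cartilages, ordered by slice.
#'
#' @param participant_id Participant identifier (scalar character).
#' @param timepoint_ms Acquisition time of the volume in milliseconds
#'   (non-negative integer; the standard protocol samples every 100 ms).
#' @param boxes A data frame with columns `slice_index`, `side`
#'   (`"left"`/`"right"`), `x_min`, `y_min`, `x_max`, `y_max` (pixels). At
#'   most one box per side per slice; slices may carry one, both, or no
#'   sides.
#' @param geometry A [voxel_geometry()] the boxes must lie on.
#' @return An object of class `volume_annotation`.
#' @export
volume_annotation <- function(participant_id, timepoint_ms, boxes,
                              geometry = voxel_geometry()) {
  if (length(participant_id) != 1 || is.na(participant_id)) {
    abort_validation("`participant_id` must be a non-missing scalar.")
  }
  if (length(timepoint_ms) != 1 || !is.numeric(timepoint_ms) ||
      !is.finite(timepoint_ms) || timepoint_ms < 0 ||
      timepoint_ms != round(timepoint_ms)) {
    abort_validation("`timepoint_ms` must be a single non-negative integer.")
  }
  boxes <- tibble::as_tibble(boxes)
  needed <- c("slice_index", "side", "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(needed, names(boxes))
  if (length(missing_cols)) {
    abort_validation(paste0("`boxes` is missing columns: ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (nrow(boxes)) {
    if (!all(boxes$side %in% c("left", "right"))) {
      abort_validation("Box `side` must be 'left' or 'right'.")
    }
    if (anyDuplicated(boxes[, c("slice_index", "side")])) {
      abort_validation("At most one box per side is allowed on each slice.")
    }
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
      abort_validation("Degenerate bounding box: need x_min < x_max and y_min < y_max.")
    }
    if (any(boxes$x_min < 0) || any(boxes$y_min < 0) ||
        any(boxes$x_max > geometry$grid_width) ||
        any(boxes$y_max > geometry$grid_height)) {
      abort_validation("Bounding boxes extend beyond the voxel grid.")
    }
    boxes <- boxes[order(boxes$slice_index, boxes$side), , drop = FALSE]
  }
  structure(list(participant_id = as.character(participant_id),
                 timepoint_ms = as.integer(timepoint_ms),
                 boxes = boxes, geometry = geometry),
            class = "volume_annotation")
}

#' @export
print.volume_annotation <- function(x, ...) {
  cat(sprintf("<volume_annotation> %s @ %d ms: %d box(es) on %d slice(s)\n",
              x$participant_id, x$timepoint_ms, nrow(x$boxes),
              length(unique(x$boxes$slice_index))))
  invisible(x)
}

#' Manually placed fiducial marker
#'
#' A point landmark on the most medial aspect of one arytenoid cartilage,
#' in 0-based pixel coordinates plus an axial slice index.
#'
#' @param x,y Pixel coordinates on the axial slice.
#' @param slice_index Axial slice the marker sits on.
#' @param side `"left"` or `"right"`.
#' @param geometry A [voxel_geometry()] the marker must lie on.
#' @export
fiducial_marker <- function(x, y, slice_index, side = c("left", "right"),
                            geometry = voxel_geometry()) {
  side <- match.arg(side)
  if (!all(is.finite(c(x, y, slice_index)))) {
    abort_validation("Fiducial coordinates must be finite.")
  }
  if (x < 0 || x > geometry$grid_width || y < 0 || y > geometry$grid_height) {
    abort_validation("Fiducial marker lies outside the voxel grid.")
  }
  structure(list(x = x, y = y, slice_index = as.integer(slice_index), side = side),
            class = "fiducial_marker")
}

#' One timepoint's manual observer output
#'
#' The pair of fiducial markers (left and right arytenoid) placed by the
#' manual observer, plus the axial slice the observer chose to measure on.
#'
#' @param participant_id,timepoint_ms Identify the volume (as in
#'   [volume_annotation()]).
#' @param left,right [fiducial_marker()] objects with matching `side` labels.
#' @param manual_slice_index The axial slice the observer selected; defaults
#'   to the left marker's slice.
#' @export
fiducial_pair <- function(participant_id, timepoint_ms, left, right,
                          manual_slice_index = left$slice_index) {
  stopifnot(inherits(left, "fiducial_marker"), inherits(right, "fiducial_marker"))
  if (left$side != "left" || right$side != "right") {
    abort_validation("`left` must carry side 'left' and `right` side 'right'.")
  }
  if (length(timepoint_ms) != 1 || timepoint_ms < 0 ||
      timepoint_ms != round(timepoint_ms)) {
    abort_validation("`timepoint_ms` must be a single non-negative integer.")
  }
  structure(list(participant_id = as.character(participant_id),
                 timepoint_ms = as.integer(timepoint_ms),
                 left = left, right = right,
                 manual_slice_index = as.integer(manual_slice_index)),
            class = "fiducial_pair")
}
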