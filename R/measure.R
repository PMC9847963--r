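#' Manual inter-arytenoid distance (IAD_M)
#'
#' The 3-D Euclidean distance between the two paired fiducial markers, with
#' anisotropic scaling of each axis by its voxel spacing:
#' `sqrt((dx*sx)^2 + (dy*sy)^2 + (dz*sz)^2)`. When both markers share a
#' slice (`dz = 0`) this reduces to the in-plane distance; cross-slice
#' marker pairs are supported because the observer scrolls freely through
#' the image stack.
#'
#' @param pair A [fiducial_pair()].
#' @param geometry A [voxel_geometry()].
#' @return Distance in mm (scalar, >= 0).
#' @export
iad_manual <- function(pair, geometry = voxel_geometry()) {
  stopifnot(inherits(pair, "fiducial_pair"))
  dx <- (pair$right$x - pair$left$x) * geometry$pixel_size_x
  dy <- (pair$right$y - pair$left$y) * geometry$pixel_size_y
  dz <- (pair$right$slice_index - pair$left$slice_index) * geometry$slice_thickness
  sqrt(dx^2 + dy^2 + dz^2)
}

# Per-slice left/right gap table for one volume; only slices carrying both
# sides qualify.
slice_gap_table <- function(volume) {
  b <- volume$boxes
  l <- b[b$side == "left", c("slice_index", "x_min", "x_max")]
  r <- b[b$side == "right", c("slice_index", "x_min", "x_max")]
  m <- merge(l, r, by = "slice_index", suffixes = c("_l", "_r"))
  if (!nrow(m)) {
    return(tibble::tibble(slice_index = integer(), gap_mm = numeric()))
  }
  m <- m[order(m$slice_index), ]
  tibble::tibble(
    slice_index = as.integer(m$slice_index),
    gap_mm = gap_px(m$x_min_l, m$x_max_l, m$x_min_r, m$x_max_r) *
      volume$geometry$pixel_size_x
  )
}

#' Automated inter-arytenoid distance (IAD_A)
#'
#' The detector estimate for one timepoint: the minimum left/right box gap
#' over all axial slices on which both arytenoid cartilages were localized.
#' Ties are broken toward the lowest slice index so the reported argmin
#' slice is deterministic.
#'
#' @param volume A [volume_annotation()].
#' @param geometry A [voxel_geometry()]; defaults to the geometry stored in
#'   `volume`.
#' @return A list with `iad_mm` (minimum gap, mm) and `argmin_slice`. When
#'   no slice carries both boxes the timepoint is unusable for IAD_A and
#'   both fields are `NA` (a missing-result signal, not an error).
#' @export
iad_auto <- function(volume, geometry = NULL) {
  stopifnot(inherits(volume, "volume_annotation"))
  if (!is.null(geometry)) volume$geometry <- geometry
  gaps <- slice_gap_table(volume)
  if (!nrow(gaps)) {
    return(list(iad_mm = NA_real_, argmin_slice = NA_integer_))
  }
  i <- which.min(gaps$gap_mm) # which.min takes the first (lowest slice) on ties
  list(iad_mm = gaps$gap_mm[i], argmin_slice = gaps$slice_index[i])
}

#' Same-slice automated inter-arytenoid distance (IAD_S)
#'
#' The detector's box gap evaluated on exactly the axial slice the manual
#' observer measured on. Comparing IAD_S with IAD_M removes the bias
#' component attributable to slice selection, leaving within-slice marking
#' differences.
#'
#' @param volume A [volume_annotation()].
#' @param manual_slice_index The observer's slice. Must fall inside the
#'   volume's annotated slice range (outside is a validation error, distinct
#'   from the missing/excluded state below).
#' @param geometry Optional [voxel_geometry()] override.
#' @return Gap in mm, or `NA_real_` when the detector did not localize a
#'   left/right pair on that slice (the data point is then excluded from
#'   the same-slice comparison).
#' @export
iad_same_slice <- function(volume, manual_slice_index, geometry = NULL) {
  stopifnot(inherits(volume, "volume_annotation"))
  if (!is.null(geometry)) volume$geometry <- geometry
  if (!nrow(volume$boxes)) {
    abort_validation("Volume carries no boxes; no slice range to index into.")
  }
  rng <- range(volume$boxes$slice_index)
  if (length(manual_slice_index) != 1 || !is.finite(manual_slice_index) ||
      manual_slice_index < rng[1] || manual_slice_index > rng[2]) {
    abort_validation(sprintf(
      "`manual_slice_index` (%s) outside the volume's slice range [%d, %d].",
      format(manual_slice_index), rng[1], rng[2]))
  }
  gaps <- slice_gap_table(volume)
  hit <- gaps$gap_mm[gaps$slice_index == manual_slice_index]
  if (!length(hit)) NA_real_ else hit
}

box_table_schema <- c("participant_id", "timepoint_ms", "slice_index", "side",
                      "x_min", "y_min", "x_max", "y_max")
fiducial_table_schema <- c("participant_id", "timepoint_ms", "side",
                           "x_px", "y_px", "slice_index", "manual_slice_index")

check_schema <- function(df, schema, what) {
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    abort_validation(paste0(what, " is missing columns: ",
                            paste(missing_cols, collapse = ", ")))
  }
}

#' Pair automated and manual annotations into joint IAD measurements
#'
#' Joins detector box stacks and manual fiducial pairs on the key
#' `(participant_id, timepoint_ms)` and computes, per matched timepoint,
#' IAD_M, IAD_A (with its argmin slice), and IAD_S. Keys present in only one
#' source, and timepoints where no slice carries both boxes (IAD_A
#' undefined), are dropped with a warning that reports the counts; a missing
#' IAD_S, by contrast, is a data state recorded in `s_excluded`.
#'
#' @param boxes Detector output table (schema of `boxes.csv`):
#'   `participant_id, timepoint_ms, slice_index, side, x_min, y_min, x_max,
#'   y_max`.
#' @param fiducials Manual output table (schema of `fiducials.csv`):
#'   `participant_id, timepoint_ms, side, x_px, y_px, slice_index,
#'   manual_slice_index`, two rows (left + right) per timepoint.
#' @param geometry A [voxel_geometry()].
#' @return A tibble with one row per matched timepoint:
#'   `participant_id, timepoint_ms, iad_m_mm, iad_a_mm, iad_s_mm,
#'   s_excluded, argmin_slice`. Attribute `dropped` carries the counts of
#'   unmatched/unusable keys.
#' @export
pair_timepoints <- function(boxes, fiducials, geometry = voxel_geometry()) {
  boxes <- tibble::as_tibble(boxes)
  fiducials <- tibble::as_tibble(fiducials)
  check_schema(boxes, box_table_schema, "`boxes`")
  check_schema(fiducials, fiducial_table_schema, "`fiducials`")
  if (anyDuplicated(boxes[, c("participant_id", "timepoint_ms", "slice_index", "side")])) {
    abort_validation("`boxes` contains duplicate (participant, timepoint, slice, side) rows.")
  }
  if (anyDuplicated(fiducials[, c("participant_id", "timepoint_ms", "side")])) {
    abort_validation("`fiducials` contains duplicate (participant, timepoint, side) rows.")
  }

  key <- function(df) paste(df$participant_id, df$timepoint_ms, sep = "\r")
  box_keys <- unique(key(boxes))
  fid_keys <- unique(key(fiducials))
  shared <- intersect(box_keys, fid_keys)
  n_box_only <- length(setdiff(box_keys, fid_keys))
  n_fid_only <- length(setdiff(fid_keys, box_keys))

  rows <- vector("list", length(shared))
  n_no_auto <- 0L
  boxes_split <- split(boxes, key(boxes))
  fids_split <- split(fiducials, key(fiducials))

  for (i in seq_along(shared)) {
    k <- shared[i]
    b <- boxes_split[[k]]
    f <- fids_split[[k]]
    pid <- b$participant_id[1]
    tp <- b$timepoint_ms[1]
    fl <- f[f$side == "left", ]
    fr <- f[f$side == "right", ]
    if (nrow(fl) != 1 || nrow(fr) != 1) {
      abort_validation(sprintf(
        "Fiducials for %s @ %s ms must have exactly one left and one right row.",
        pid, tp))
    }
    vol <- volume_annotation(pid, tp, b[, c("slice_index", "side", "x_min",
                                            "y_min", "x_max", "y_max")],
                             geometry = geometry)
    pair <- fiducial_pair(
      pid, tp,
      left = fiducial_marker(fl$x_px, fl$y_px, fl$slice_index, "left", geometry),
      right = fiducial_marker(fr$x_px, fr$y_px, fr$slice_index, "right", geometry),
      manual_slice_index = fl$manual_slice_index
    )
    auto <- iad_auto(vol)
    if (is.na(auto$iad_mm)) {
      n_no_auto <- n_no_auto + 1L
      next
    }
    s <- tryCatch(
      iad_same_slice(vol, pair$manual_slice_index),
      iadct_validation_error = function(e) {
        abort_validation(sprintf("%s (participant %s, timepoint %s ms)",
                                 conditionMessage(e), pid, tp))
      })
    rows[[i]] <- tibble::tibble(
      participant_id = pid,
      timepoint_ms = as.integer(tp),
      iad_m_mm = iad_manual(pair, geometry),
      iad_a_mm = auto$iad_mm,
      iad_s_mm = s,
      s_excluded = is.na(s),
      argmin_slice = auto$argmin_slice
    )
  }

  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- out[order(out$participant_id, out$timepoint_ms), ]
  } else {
    out <- tibble::tibble(participant_id = character(), timepoint_ms = integer(),
                          iad_m_mm = numeric(), iad_a_mm = numeric(),
                          iad_s_mm = numeric(), s_excluded = logical(),
                          argmin_slice = integer())
  }
  dropped <- c(boxes_only = n_box_only, fiducials_only = n_fid_only,
               no_auto_iad = n_no_auto)
  if (sum(dropped) > 0) {
    warn_iadct(sprintf(
      "Dropped timepoints: %d only in boxes, %d only in fiducials, %d without a usable IAD_A.",
      n_box_only, n_fid_only, n_no_auto), class = "iadct_dropped_keys")
  }
  attr(out, "dropped") <- dropped
  out
}
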