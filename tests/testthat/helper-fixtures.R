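# Shared fixture builders. All synthetic, built in code at test time.

default_geom <- voxel_geometry()

# A box row in the boxes-table schema.
box_row <- function(pid, tp, slice, side, x_min, x_max,
                    y_min = 200, y_max = 240) {
  tibble::tibble(participant_id = pid, timepoint_ms = tp, slice_index = slice,
                 side = side, x_min = x_min, y_min = y_min,
                 x_max = x_max, y_max = y_max)
}

# A volume whose per-slice gaps (in pixels between facing edges) are given by
# `gaps_px`, named by slice index; NA drops the right box on that slice.
toy_volume <- function(gaps_px, pid = "p1", tp = 0L) {
  rows <- list()
  for (i in seq_along(gaps_px)) {
    slice <- as.integer(names(gaps_px)[i])
    rows[[length(rows) + 1]] <- box_row(pid, tp, slice, "left", 100, 200)
    if (!is.na(gaps_px[i])) {
      rows[[length(rows) + 1]] <-
        box_row(pid, tp, slice, "right", 200 + gaps_px[i], 300 + gaps_px[i])
    }
  }
  volume_annotation(pid, tp, dplyr::bind_rows(rows)[, -(1:2)])
}

# Fiducial rows (left + right) in the fiducials-table schema.
fiducial_rows <- function(pid, tp, xl, xr, slice = 10L, y = 250,
                          manual_slice = slice) {
  tibble::tibble(participant_id = pid, timepoint_ms = tp,
                 side = c("left", "right"), x_px = c(xl, xr), y_px = y,
                 slice_index = slice, manual_slice_index = manual_slice)
}

# Brute-force oracle for the minimum-over-slices automated IAD: enumerate
# every slice, recompute each gap from the raw box edges, take the minimum.
oracle_iad_auto <- function(volume, geometry = default_geom) {
  b <- volume$boxes
  slices <- sort(unique(b$slice_index))
  best <- Inf; best_slice <- NA_integer_
  for (s in slices) {
    l <- b[b$slice_index == s & b$side == "left", ]
    r <- b[b$slice_index == s & b$side == "right", ]
    if (nrow(l) != 1 || nrow(r) != 1) next
    lo <- if ((l$x_min + l$x_max) / 2 <= (r$x_min + r$x_max) / 2) l else r
    hi <- if ((l$x_min + l$x_max) / 2 <= (r$x_min + r$x_max) / 2) r else l
    g <- max(0, hi$x_min - lo$x_max) * geometry$pixel_size_x
    if (g < best) { best <- g; best_slice <- s }
  }
  if (is.infinite(best)) list(iad_mm = NA_real_, argmin_slice = NA_integer_)
  else list(iad_mm = best, argmin_slice = best_slice)
}

# Method-of-moments (ANOVA) oracle for the one-way variance-components
# model, written independently of the package implementation.
oracle_moments <- function(participant_id, difference) {
  g <- split(difference, participant_id)
  k <- length(g); N <- length(difference)
  ni <- lengths(g)
  means <- vapply(g, mean, numeric(1))
  grand <- mean(difference)
  msw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / (N - k)
  msb <- sum(ni * (means - grand)^2) / (k - 1)
  c0 <- (N - sum(ni^2) / N) / (k - 1)
  list(bias = grand, sigma_w = sqrt(msw),
       sigma_b = sqrt(max(0, (msb - msw) / c0)))
}

# A small zero-noise simulation config for round-trip tests.
noiseless_config <- function(...) {
  simulation_config(n_participants = 3, participant_sd_mm = 0,
                    marking_bias_mm = 0, slice_selection_bias_mm = 0,
                    within_noise_sd_mm = 0, between_bias_sd_mm = 0,
                    artifact_rate = 0, artifact_magnitude_mm = 0,
                    exclusion_rate = 0, seed = 11, ...)
}
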