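#' Configuration of the synthetic 4D laryngeal CT cohort
#'
#' All knobs of the annotation generator. The defaults describe the standard
#' validation world: 12 participants scanned for 5 s at 100 ms intervals
#' while producing five phonations, on the default [voxel_geometry()] grid;
#' a manual-vs-automated difference made of a 0.52 mm within-slice marking
#' bias plus a 1.0 mm slice-selection bias; participant-level heterogeneity
#' of the difference of 0.73 mm; and rest-phase detector artifacts plus an
#' 8% detector-miss (IAD_S exclusion) rate.
#'
#' @param n_participants Cohort size.
#' @param acquisition_s Continuous imaging period, seconds.
#' @param sample_interval_ms Sampling interval of the dynamic volumes, ms.
#' @param n_phonations Number of adduction pulses across the acquisition.
#' @param rest_iad_mm True IAD at vocal rest (arytenoids abducted), mm.
#' @param phonation_iad_mm True IAD at the phonation trough (adducted), mm.
#' @param participant_sd_mm SD of the participant-level offset applied to
#'   the whole true trajectory (anatomical size variation), mm.
#' @param marking_bias_mm Mean within-slice manual-vs-automated marking
#'   offset, mm.
#' @param slice_selection_bias_mm Mean extra manual offset caused by
#'   imperfect slice choice, mm. Injected mechanistically: the manual slice
#'   is displaced into a region of the convex through-slice gap profile
#'   whose gap exceeds the minimum by this amount on average.
#' @param within_noise_sd_mm SD of the per-timepoint measurement noise
#'   applied independently to the manual marking and to the automated gap
#'   profile, mm.
#' @param between_bias_sd_mm SD of the participant-level component of the
#'   manual-vs-automated difference, mm.
#' @param artifact_rate Probability that a rest-phase timepoint carries an
#'   artifactual automated underestimate (one slice's gap collapses).
#' @param artifact_magnitude_mm Size of the artifactual reduction, mm.
#' @param exclusion_rate Probability that the detector misses the box pair
#'   on the manually chosen slice (IAD_S then excluded).
#' @param n_slices Axial slices spanning the larynx.
#' @param slice_curvature_mm Curvature of the through-slice gap profile,
#'   mm per slice^2 away from the minimal slice.
#' @param seed Master seed; every participant derives reproducible
#'   substreams from it.
#' @return An object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(n_participants = 12L,
                              acquisition_s = 5,
                              sample_interval_ms = 100,
                              n_phonations = 5L,
                              rest_iad_mm = 10,
                              phonation_iad_mm = 4.7,
                              participant_sd_mm = 1.0,
                              marking_bias_mm = 0.52,
                              slice_selection_bias_mm = 1.0,
                              within_noise_sd_mm = 0.8,
                              between_bias_sd_mm = 0.73,
                              artifact_rate = 0.05,
                              artifact_magnitude_mm = 4,
                              exclusion_rate = 0.08,
                              n_slices = 21L,
                              slice_curvature_mm = 0.4,
                              seed = 1L) {
  cfg <- list(n_participants = n_participants, acquisition_s = acquisition_s,
              sample_interval_ms = sample_interval_ms,
              n_phonations = n_phonations, rest_iad_mm = rest_iad_mm,
              phonation_iad_mm = phonation_iad_mm,
              participant_sd_mm = participant_sd_mm,
              marking_bias_mm = marking_bias_mm,
              slice_selection_bias_mm = slice_selection_bias_mm,
              within_noise_sd_mm = within_noise_sd_mm,
              between_bias_sd_mm = between_bias_sd_mm,
              artifact_rate = artifact_rate,
              artifact_magnitude_mm = artifact_magnitude_mm,
              exclusion_rate = exclusion_rate, n_slices = n_slices,
              slice_curvature_mm = slice_curvature_mm, seed = seed)
  problems <- character()
  need_count <- c("n_participants", "n_phonations", "n_slices")
  for (f in need_count) {
    if (!is_count(cfg[[f]])) problems <- c(problems, sprintf("`%s` must be a positive integer.", f))
  }
  need_nonneg <- c("participant_sd_mm", "marking_bias_mm",
                   "slice_selection_bias_mm", "within_noise_sd_mm",
                   "between_bias_sd_mm", "artifact_magnitude_mm",
                   "phonation_iad_mm")
  for (f in need_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      problems <- c(problems, sprintf("`%s` must be a single non-negative number.", f))
    }
  }
  for (f in c("artifact_rate", "exclusion_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      problems <- c(problems, sprintf("`%s` must lie in [0, 1].", f))
    }
  }
  if (!is.numeric(cfg$acquisition_s) || cfg$acquisition_s <= 0) {
    problems <- c(problems, "`acquisition_s` must be positive.")
  }
  if (!is_count(cfg$sample_interval_ms)) {
    problems <- c(problems, "`sample_interval_ms` must be a positive integer.")
  }
  if (is.numeric(cfg$rest_iad_mm) && is.numeric(cfg$phonation_iad_mm) &&
      !(cfg$rest_iad_mm > cfg$phonation_iad_mm)) {
    problems <- c(problems, "`rest_iad_mm` must exceed `phonation_iad_mm`.")
  }
  if (!is.numeric(cfg$slice_curvature_mm) || cfg$slice_curvature_mm <= 0) {
    problems <- c(problems, "`slice_curvature_mm` must be positive.")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed) ||
      cfg$seed != round(cfg$seed)) {
    problems <- c(problems, "`seed` must be a single integer.")
  }
  if (!length(problems)) {
    n_t <- cfg$acquisition_s * 1000 / cfg$sample_interval_ms
    if (abs(n_t - round(n_t)) > 1e-9) {
      problems <- c(problems, "`acquisition_s` must be a whole number of sampling intervals.")
    }
    off <- slice_offset_dist(cfg)
    if (is_count(cfg$n_slices) && (cfg$n_slices %/% 2 - SLICE_BAND < 0 ||
                                   off$m > SLICE_BAND)) {
      problems <- c(problems, sprintf(
        "`n_slices` too small or `slice_selection_bias_mm` too large for the +/-%d-slice detection band.",
        SLICE_BAND))
    }
  }
  if (length(problems)) {
    abort_validation(c("Invalid simulation configuration:",
                       stats::setNames(problems, rep("x", length(problems)))))
  }
  cfg$n_participants <- as.integer(cfg$n_participants)
  cfg$n_phonations <- as.integer(cfg$n_phonations)
  cfg$n_slices <- as.integer(cfg$n_slices)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "simulation_config")
}

# Slices on which the detector can see the cartilages: the minimal-gap slice
# plus/minus this band.
SLICE_BAND <- 4L

# Distribution of the manual slice-selection offset delta (in slices):
# three-point on {-m, 0, +m} with P(+-m) = q/2 calibrated so that
# E[curvature * delta^2] equals slice_selection_bias_mm exactly.
slice_offset_dist <- function(config) {
  bias <- config$slice_selection_bias_mm
  if (bias <= 0) return(list(m = 0L, q = 0))
  m <- as.integer(ceiling(sqrt(bias / config$slice_curvature_mm)))
  list(m = m, q = bias / (config$slice_curvature_mm * m^2))
}

n_timepoints <- function(config) {
  as.integer(round(config$acquisition_s * 1000 / config$sample_interval_ms))
}

participant_label <- function(i) sprintf("P%02d", i)

#' Simulate one participant's true IAD trajectory
#'
#' The true inter-arytenoid distance alternates smoothly between a rest
#' baseline (vocal folds abducted) and phonation troughs (adducted), as a
#' train of raised-cosine adduction pulses: the acquisition is split into
#' `n_phonations` equal segments and within each the adduction depth is
#' `(1 - cos(2*pi*u))/2` for segment fraction `u`. A participant-level
#' offset (SD `participant_sd_mm`) shifts the whole trajectory. Timepoints
#' with adduction depth >= 0.5 are labeled `"phonation"`, the rest
#' `"rest"`. Deterministic given `(config$seed, participant_index)`.
#'
#' @param config A [simulation_config()].
#' @param participant_index Integer in `1:n_participants`.
#' @return A tibble with `participant_id`, `participant_index`,
#'   `timepoint_ms`, `true_iad_mm`, `phase`, `participant_offset_mm`.
#' @export
simulate_trajectory <- function(config, participant_index) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(participant_index) || participant_index > config$n_participants) {
    abort_validation("`participant_index` must be in 1..n_participants.")
  }
  offset <- with_seed(derive_seed(config$seed, participant_index, 1L),
                      stats::rnorm(1, 0, config$participant_sd_mm))
  n_t <- n_timepoints(config)
  t_ms <- (seq_len(n_t) - 1L) * config$sample_interval_ms
  seg_ms <- config$acquisition_s * 1000 / config$n_phonations
  u <- (t_ms %% seg_ms) / seg_ms
  depth <- (1 - cos(2 * pi * u)) / 2
  rest_i <- config$rest_iad_mm + offset
  phon_i <- max(0, config$phonation_iad_mm + offset)
  true_iad <- pmax(0, rest_i - (rest_i - phon_i) * depth)
  tibble::tibble(
    participant_id = participant_label(participant_index),
    participant_index = as.integer(participant_index),
    timepoint_ms = as.integer(t_ms),
    true_iad_mm = true_iad,
    phase = ifelse(depth >= 0.5, "phonation", "rest"),
    participant_offset_mm = offset
  )
}

# All per-timepoint latent draws shared by the manual and automated
# annotation builders, drawn in a fixed order from one participant
# substream so that both builders (and repeated calls) see identical
# values.
simulate_latents <- function(config, participant_index) {
  off <- slice_offset_dist(config)
  n_t <- n_timepoints(config)
  with_seed(derive_seed(config$seed, participant_index, 2L), {
    diff_offset <- stats::rnorm(1, 0, config$between_bias_sd_mm)
    delta_u <- stats::runif(n_t)
    eta <- stats::rnorm(n_t, 0, config$within_noise_sd_mm)     # manual noise
    eps <- stats::rnorm(n_t, 0, config$within_noise_sd_mm)     # profile noise
    artifact_u <- stats::runif(n_t)
    artifact_pick <- stats::runif(n_t)
    excl_u <- stats::runif(n_t)
    delta <- ifelse(delta_u < off$q / 2, -off$m,
                    ifelse(delta_u < off$q, off$m, 0L))
    list(diff_offset = diff_offset, delta = as.integer(delta),
         eta = eta, eps = eps, artifact_u = artifact_u,
         artifact_pick = artifact_pick, excl_u = excl_u)
  })
}

#' Simulate the manual observer's fiducial annotations
#'
#' Places one left and one right fiducial marker per timepoint,
#' midline-symmetric on the axial grid, such that the implied manual IAD
#' equals the true IAD plus the slice-selection elevation
#' (`curvature * delta^2` for the drawn slice offset `delta`), the
#' within-slice marking bias, a participant-level difference offset, and
#' within-timepoint noise. Marker coordinates are snapped to integer pixels
#' last, so sub-pixel quantization (at most one in-plane pixel, 0.222 mm by
#' default) is part of the realistic noise floor. Negative implied
#' distances are clamped to zero and counted in a warning.
#'
#' @param trajectory Output of [simulate_trajectory()] for one participant.
#' @param config The same [simulation_config()].
#' @param geometry A [voxel_geometry()].
#' @return A tibble in the `fiducials.csv` schema: `participant_id,
#'   timepoint_ms, side, x_px, y_px, slice_index, manual_slice_index`.
#' @export
simulate_manual_annotation <- function(trajectory, config,
                                       geometry = voxel_geometry()) {
  stopifnot(inherits(config, "simulation_config"))
  idx <- trajectory$participant_index[1]
  lat <- simulate_latents(config, idx)
  z_star <- config$n_slices %/% 2L
  elev <- config$slice_curvature_mm * lat$delta^2
  target <- trajectory$true_iad_mm + elev + config$marking_bias_mm +
    lat$diff_offset + lat$eta
  n_clamped <- sum(target < 0)
  if (n_clamped > 0) {
    warn_iadct(sprintf("%d negative manual IAD target(s) clamped to 0.", n_clamped),
               class = "iadct_clamped_iad")
    target <- pmax(0, target)
  }
  x_c <- geometry$grid_width / 2
  half_px <- target / (2 * geometry$pixel_size_x)
  x_left <- round(x_c - half_px)
  x_right <- round(x_c + half_px)
  y_px <- round(geometry$grid_height / 2)
  z_m <- z_star + lat$delta
  n_t <- nrow(trajectory)
  tibble::tibble(
    participant_id = rep(trajectory$participant_id, 2),
    timepoint_ms = rep(trajectory$timepoint_ms, 2),
    side = rep(c("left", "right"), each = n_t),
    x_px = c(x_left, x_right),
    y_px = rep(y_px, 2 * n_t),
    slice_index = rep(as.integer(z_m), 2),
    manual_slice_index = rep(as.integer(z_m), 2)
  )[order(rep(seq_len(n_t), 2)), ]
}

#' Simulate the automated detector's bounding-box stacks
#'
#' For each timepoint, builds a stack of axial slices within a fixed band
#' around the minimal-gap slice whose left/right box gaps follow a convex
#' through-slice profile `true_iad + noise + curvature * (z - z*)^2`
#' (clamped at 0). With probability `artifact_rate` -- during vocal rest
#' only, matching where automated outliers occur -- one random slice's gap
#' collapses to `artifact_magnitude_mm` below the stack minimum (clamped at
#' 0), so the minimum-over-slices IAD_A severely underestimates. With probability `exclusion_rate` the box pair
#' on the manually selected slice is dropped (a detector miss: IAD_S is
#' then excluded). Box edges are snapped to integer pixels last.
#'
#' @inheritParams simulate_manual_annotation
#' @return A tibble in the `boxes.csv` schema, with attribute `latents`
#'   (the per-timepoint latent table used, for truth bookkeeping).
#' @export
simulate_automated_boxes <- function(trajectory, config,
                                     geometry = voxel_geometry()) {
  stopifnot(inherits(config, "simulation_config"))
  idx <- trajectory$participant_index[1]
  lat <- simulate_latents(config, idx)
  z_star <- config$n_slices %/% 2L
  band <- (z_star - SLICE_BAND):(z_star + SLICE_BAND)
  band <- band[band >= 0 & band < config$n_slices]
  n_z <- length(band)
  x_c <- geometry$grid_width / 2
  y_c <- geometry$grid_height / 2
  box_w <- 30L
  box_h <- 40L
  n_t <- nrow(trajectory)

  rows <- vector("list", n_t)
  artifact <- logical(n_t)
  missed <- logical(n_t)
  for (j in seq_len(n_t)) {
    g <- pmax(0, trajectory$true_iad_mm[j] + lat$eps[j] +
                config$slice_curvature_mm * (band - z_star)^2)
    if (trajectory$phase[j] == "rest" && lat$artifact_u[j] < config$artifact_rate) {
      artifact[j] <- TRUE
      za <- 1L + as.integer(floor(lat$artifact_pick[j] * n_z))
      za <- min(za, n_z)
      # the artifactual slice must fall below the stack minimum, else the
      # minimum-over-slices estimate would ignore it
      g[za] <- max(0, min(g) - config$artifact_magnitude_mm)
    }
    keep <- rep(TRUE, n_z)
    if (lat$excl_u[j] < config$exclusion_rate) {
      missed[j] <- TRUE
      keep[band == z_star + lat$delta[j]] <- FALSE
    }
    zk <- band[keep]
    gk <- g[keep]
    half_px <- gk / (2 * geometry$pixel_size_x)
    xl_in <- round(x_c - half_px)
    xr_in <- round(x_c + half_px)
    rows[[j]] <- tibble::tibble(
      participant_id = trajectory$participant_id[j],
      timepoint_ms = trajectory$timepoint_ms[j],
      slice_index = as.integer(rep(zk, 2)),
      side = rep(c("left", "right"), each = length(zk)),
      x_min = c(xl_in - box_w, xr_in),
      y_min = y_c - box_h / 2,
      x_max = c(xl_in, xr_in + box_w),
      y_max = y_c + box_h / 2
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "latents") <- tibble::tibble(
    timepoint_ms = trajectory$timepoint_ms,
    diff_offset_mm = lat$diff_offset,
    slice_offset = lat$delta,
    artifact = artifact,
    s_missed = missed
  )
  out
}

#' Generate a full synthetic annotation cohort
#'
#' Runs the trajectory, manual-annotation and automated-box generators for
#' every participant under one master seed and assembles the three output
#' tables plus a truth table for recovery tests. Identical configurations
#' (including the seed) give identical datasets.
#'
#' @param config A [simulation_config()].
#' @param geometry A [voxel_geometry()].
#' @return An object of class `iad_dataset`: a list with tibbles `boxes`,
#'   `fiducials`, `truth` (`participant_id, timepoint_ms, true_iad_mm,
#'   phase, participant_offset_mm, diff_offset_mm, slice_offset, artifact,
#'   s_missed`), plus the resolved `config` and `geometry`.
#' @export
generate_dataset <- function(config = simulation_config(),
                             geometry = voxel_geometry()) {
  stopifnot(inherits(config, "simulation_config"))
  boxes <- vector("list", config$n_participants)
  fids <- vector("list", config$n_participants)
  truth <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    traj <- simulate_trajectory(config, i)
    b <- simulate_automated_boxes(traj, config, geometry)
    fids[[i]] <- simulate_manual_annotation(traj, config, geometry)
    lat <- attr(b, "latents")
    attr(b, "latents") <- NULL
    boxes[[i]] <- b
    truth[[i]] <- tibble::tibble(
      participant_id = traj$participant_id,
      timepoint_ms = traj$timepoint_ms,
      true_iad_mm = traj$true_iad_mm,
      phase = traj$phase,
      participant_offset_mm = traj$participant_offset_mm,
      diff_offset_mm = lat$diff_offset_mm,
      slice_offset = lat$slice_offset,
      artifact = lat$artifact,
      s_missed = lat$s_missed
    )
  }
  structure(list(boxes = dplyr::bind_rows(boxes),
                 fiducials = dplyr::bind_rows(fids),
                 truth = dplyr::bind_rows(truth),
                 config = config, geometry = geometry),
            class = "iad_dataset")
}

#' @export
print.iad_dataset <- function(x, ...) {
  cat(sprintf("<iad_dataset> %d participants, %d timepoints, seed %d\n",
              x$config$n_participants, nrow(x$truth), x$config$seed))
  invisible(x)
}
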