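test_that("simulation config validates fields with informative messages", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(artifact_rate = 1.5),
               class = "iadct_validation_error")
  expect_error(simulation_config(n_participants = 0),
               class = "iadct_validation_error")
  expect_error(simulation_config(rest_iad_mm = 3, phonation_iad_mm = 5),
               class = "iadct_validation_error")
  expect_error(simulation_config(within_noise_sd_mm = -1),
               class = "iadct_validation_error")
  err <- tryCatch(simulation_config(artifact_rate = 2, n_slices = 0),
                  error = function(e) conditionMessage(e))
  expect_match(err, "artifact_rate")
  expect_match(err, "n_slices")
})

test_that("trajectories alternate rest and phonation on the pulse schedule", {
  cfg <- simulation_config(seed = 21)
  traj <- simulate_trajectory(cfg, 1)
  expect_equal(nrow(traj), 50)   # 5 s at 100 ms
  expect_equal(traj$timepoint_ms, seq(0, 4900, by = 100))
  # five local minima, one per phonation segment
  v <- traj$true_iad_mm
  minima <- which(diff(sign(diff(v))) > 0) + 1
  expect_equal(length(minima), 5)
  expect_equal(traj$timepoint_ms[minima], c(500, 1500, 2500, 3500, 4500))
  # closed-form pulse schedule: adduction depth >= 0.5 over the central half
  # of each 1 s segment -> 25 phonation and 25 rest timepoints
  expect_equal(sum(traj$phase == "phonation"), 25)
  expect_equal(sum(traj$phase == "rest"), 25)
  # rest-phase values exceed the phonation troughs
  expect_true(min(v[traj$phase == "rest"]) > min(v[traj$phase == "phonation"]))
  expect_true(all(v >= 0))
})

test_that("participant offsets are reproducible and degenerate to a shared curve", {
  cfg <- simulation_config(seed = 22)
  expect_identical(simulate_trajectory(cfg, 3), simulate_trajectory(cfg, 3))
  expect_false(isTRUE(all.equal(simulate_trajectory(cfg, 1)$true_iad_mm,
                                simulate_trajectory(cfg, 2)$true_iad_mm)))
  flat_cfg <- simulation_config(participant_sd_mm = 0, seed = 22)
  expect_equal(simulate_trajectory(flat_cfg, 1)$true_iad_mm,
               simulate_trajectory(flat_cfg, 2)$true_iad_mm)
})

test_that("zero-noise generator round-trips within one-pixel quantization", {
  cfg <- noiseless_config()
  ds <- generate_dataset(cfg)
  out <- pair_timepoints(ds$boxes, ds$fiducials)
  tr <- dplyr::inner_join(out, ds$truth, by = c("participant_id", "timepoint_ms"))
  quant <- ds$geometry$pixel_size_x  # 0.222 mm
  expect_true(all(abs(tr$iad_m_mm - tr$true_iad_mm) <= quant + 1e-12))
  expect_equal(tr$iad_m_mm, tr$iad_a_mm)
  expect_equal(tr$iad_m_mm, tr$iad_s_mm)
})

test_that("generated bias components converge to their configured means", {
  # Large cohort, no artifacts/exclusions: mean(IAD_M - IAD_S) -> marking
  # bias; mean(IAD_M - IAD_A) -> marking + slice-selection bias.
  cfg <- simulation_config(n_participants = 40, artifact_rate = 0,
                           exclusion_rate = 0, between_bias_sd_mm = 0,
                           seed = 23)
  ds <- generate_dataset(cfg)
  m <- pair_timepoints(ds$boxes, ds$fiducials)
  d_s <- mean(m$iad_m_mm - m$iad_s_mm)
  d_a <- mean(m$iad_m_mm - m$iad_a_mm)
  # n = 2000; within-noise SE ~ 0.025 mm, slice-offset SE ~ 0.02 mm
  expect_equal(d_s, cfg$marking_bias_mm, tolerance = 0.15)
  expect_equal(d_a, cfg$marking_bias_mm + cfg$slice_selection_bias_mm,
               tolerance = 0.12)
})

test_that("artifacts fire only during vocal rest and depress IAD_A", {
  cfg <- simulation_config(artifact_rate = 1, artifact_magnitude_mm = 4,
                           exclusion_rate = 0, within_noise_sd_mm = 0,
                           between_bias_sd_mm = 0, participant_sd_mm = 0,
                           marking_bias_mm = 0, slice_selection_bias_mm = 0,
                           seed = 24)
  ds <- generate_dataset(cfg)
  m <- pair_timepoints(ds$boxes, ds$fiducials)
  tr <- dplyr::inner_join(m, ds$truth, by = c("participant_id", "timepoint_ms"))
  rest <- tr[tr$phase == "rest", ]
  phon <- tr[tr$phase == "phonation", ]
  expect_true(all(tr$artifact == (tr$phase == "rest")))
  # every rest timepoint's automated estimate is reduced by ~ the magnitude
  expect_true(all(rest$true_iad_mm - rest$iad_a_mm >
                    cfg$artifact_magnitude_mm - 2 * 0.222))
  # phonation timepoints are untouched (quantization only)
  expect_true(all(abs(phon$true_iad_mm - phon$iad_a_mm) <= 0.222 + 1e-12))
  # phonation-phase bias does not depend on the artifact rate
  cfg0 <- simulation_config(artifact_rate = 0, artifact_magnitude_mm = 4,
                            exclusion_rate = 0, within_noise_sd_mm = 0,
                            between_bias_sd_mm = 0, participant_sd_mm = 0,
                            marking_bias_mm = 0, slice_selection_bias_mm = 0,
                            seed = 24)
  m0 <- pair_timepoints(generate_dataset(cfg0)$boxes,
                        generate_dataset(cfg0)$fiducials)
  tr0 <- dplyr::inner_join(m0, generate_dataset(cfg0)$truth,
                           by = c("participant_id", "timepoint_ms"))
  phon0 <- tr0[tr0$phase == "phonation", ]
  expect_equal(mean(phon$iad_m_mm - phon$iad_a_mm),
               mean(phon0$iad_m_mm - phon0$iad_a_mm))
})

test_that("detector misses on the manual slice drive IAD_S exclusions exactly", {
  cfg <- simulation_config(exclusion_rate = 0.3, artifact_rate = 0, seed = 25)
  ds <- generate_dataset(cfg)
  m <- pair_timepoints(ds$boxes, ds$fiducials)
  tr <- dplyr::inner_join(m, ds$truth, by = c("participant_id", "timepoint_ms"))
  expect_identical(tr$s_excluded, tr$s_missed)
  expect_equal(sum(is.na(m$iad_s_mm)), sum(ds$truth$s_missed))
  expect_gt(sum(ds$truth$s_missed), 0)
})

test_that("the full generator is deterministic and scale-faithful", {
  cfg <- simulation_config(seed = 26)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$boxes, ds2$boxes)
  expect_identical(ds1$fiducials, ds2$fiducials)
  expect_identical(ds1$truth, ds2$truth)
  # study scale: 12 participants at 5 s / 100 ms -> at most 600 timepoints
  expect_lte(nrow(ds1$truth), 600)
  expect_equal(nrow(ds1$truth), 12 * 50)
  # different seeds give different data
  expect_false(identical(generate_dataset(simulation_config(seed = 27))$fiducials,
                         ds1$fiducials))
})

test_that("written datasets are byte-identical across runs with one seed", {
  cfg <- simulation_config(n_participants = 2, seed = 28)
  d1 <- file.path(tempdir(), "iadct_ds1"); d2 <- file.path(tempdir(), "iadct_ds2")
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("boxes.csv", "fiducials.csv", "truth.csv", "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated timepoints satisfy the geometric ordering IAD_A <= IAD_S", {
  ds <- generate_dataset(simulation_config(seed = 29))
  m <- pair_timepoints(ds$boxes, ds$fiducials)
  ok <- !is.na(m$iad_s_mm)
  expect_true(all(m$iad_a_mm[ok] <= m$iad_s_mm[ok] + 1e-9))
})
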