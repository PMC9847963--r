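test_that("variance components on hand-checkable toys match the moments oracle", {
  # no variation at all
  flat <- tibble::tibble(participant_id = rep(c("a", "b", "c"), each = 3),
                         difference = 2.5)
  expect_warning(vc <- fit_variance_components(flat),
                 class = "iadct_degenerate_fit")
  expect_equal(vc$bias, 2.5)
  expect_equal(vc$sigma_between, 0)
  expect_equal(vc$sigma_within, 0)

  # perfect within-participant agreement, between-participant spread
  toy <- tibble::tibble(participant_id = rep(c("a", "b"), each = 2),
                        difference = c(1, 1, 3, 3))
  for (method in c("reml", "moments")) {
    vt <- fit_variance_components(toy, method = method)
    expect_equal(vt$bias, 2)
    expect_equal(vt$sigma_within, 0)
    expect_equal(vt$sigma_between, sqrt(2), tolerance = 1e-9)
  }

  # single participant: between variance unidentifiable
  one <- tibble::tibble(participant_id = "a", difference = c(1, 2, 3))
  expect_error(fit_variance_components(one),
               class = "iadct_identifiability_error")
})

test_that("REML and moments agree on balanced designs with interior solutions", {
  set.seed(501)
  for (rep in 1:8) {
    d <- simulate_differences(6, 10, mu = runif(1, -1, 2),
                              sigma_b = runif(1, 0.5, 1.5),
                              sigma_w = runif(1, 0.3, 1))
    mom <- fit_variance_components(d, method = "moments")
    if (mom$truncated) next  # boundary case: estimators legitimately differ
    reml <- fit_variance_components(d, method = "reml")
    expect_equal(reml$bias, mom$bias, tolerance = 1e-6)
    expect_equal(reml$sigma_within, mom$sigma_within, tolerance = 1e-6)
    expect_equal(reml$sigma_between, mom$sigma_between, tolerance = 1e-6)
    # and against the independently written oracle
    orc <- oracle_moments(d$participant_id, d$difference)
    expect_equal(mom$bias, orc$bias)
    expect_equal(mom$sigma_within, orc$sigma_w)
    expect_equal(mom$sigma_between, orc$sigma_b)
  }
})

test_that("REML matches the established mixed-model fitter on unbalanced data", {
  d <- simulate_differences(9, 40, mu = 1.2, sigma_b = 0.6, sigma_w = 1.3,
                            seed = 502)
  d <- d[-sample(seq_len(nrow(d)), 37), ]
  vc <- fit_variance_components(d, method = "reml")
  fit <- lme4::lmer(difference ~ 1 + (1 | participant_id), data = d, REML = TRUE)
  sds <- as.data.frame(lme4::VarCorr(fit))$sdcor
  expect_equal(vc$bias, unname(lme4::fixef(fit)), tolerance = 1e-5)
  expect_equal(vc$sigma_between, sds[1], tolerance = 1e-5)
  expect_equal(vc$sigma_within, sds[2], tolerance = 1e-5)
})

test_that("negative between-participant variance is truncated at zero", {
  # groups with identical means but within-group spread: MSB < MSW
  d <- tibble::tibble(participant_id = rep(c("a", "b", "c"), each = 4),
                      difference = rep(c(-1, 1, -2, 2), times = 3))
  expect_warning(mom <- fit_variance_components(d, method = "moments"),
                 class = "iadct_truncated_component")
  expect_equal(mom$sigma_between, 0)
  expect_true(mom$truncated)
  expect_warning(reml <- fit_variance_components(d, method = "reml"),
                 class = "iadct_truncated_component")
  expect_equal(reml$sigma_between, 0)
  expect_equal(reml$sigma_within, sd(d$difference), tolerance = 1e-8)
})

test_that("limits of agreement are bias +/- 1.96 total SD, symmetric, exact width", {
  vc <- variance_components(bias = 1.52, sigma_between = 0.73, sigma_within = 1.45)
  loa <- limits_of_agreement(vc)
  expect_equal(unname(loa["upper"] - vc$bias), unname(vc$bias - loa["lower"]))
  expect_equal(unname(diff(loa)), 2 * 1.96 * vc$total_sd)
  expect_equal(limits_of_agreement(variance_components(0, 0, 1)),
               c(lower = -1.96, upper = 1.96))
  expect_equal(vc$total_sd, sqrt(0.73^2 + 1.45^2))
})

test_that("bias and LoA are equivariant under constant shifts; SDs invariant", {
  d <- simulate_differences(8, 20, 0.9, 0.5, 1.1, seed = 503)
  base <- fit_variance_components(d)
  for (c_shift in c(-2.5, 0.75)) {
    shifted <- d
    shifted$difference <- shifted$difference + c_shift
    vc <- fit_variance_components(shifted)
    expect_equal(vc$bias, base$bias + c_shift, tolerance = 1e-9)
    expect_equal(vc$sigma_between, base$sigma_between, tolerance = 1e-9)
    expect_equal(vc$sigma_within, base$sigma_within, tolerance = 1e-9)
    loa_base <- limits_of_agreement(base)
    loa <- limits_of_agreement(vc)
    expect_equal(unname(loa), unname(loa_base) + c_shift, tolerance = 1e-9)
  }
})

test_that("total SD is invariant to participant relabeling and row order", {
  d <- simulate_differences(7, 15, 1.1, 0.8, 0.9, seed = 504)
  base <- fit_variance_components(d)
  relabeled <- d
  relabeled$participant_id <- factor(relabeled$participant_id,
                                     labels = sample(LETTERS[1:7]))
  shuffled <- relabeled[sample(nrow(relabeled)), ]
  vc <- fit_variance_components(shuffled)
  expect_equal(vc$total_sd, base$total_sd, tolerance = 1e-9)
  expect_equal(vc$bias, base$bias, tolerance = 1e-9)
})

test_that("pooling two copies of a dataset leaves bias and sigma_w nearly unchanged", {
  # Exact at the population level; finite-sample REML denominators shift the
  # estimates by O(1/N).
  d <- simulate_differences(10, 25, 1.3, 0.6, 1.2, seed = 505)
  pooled <- dplyr::bind_rows(d, d)
  base <- fit_variance_components(d)
  vc <- fit_variance_components(pooled)
  expect_equal(vc$bias, base$bias, tolerance = 0.02)
  expect_equal(vc$sigma_within, base$sigma_within, tolerance = 0.02)
})

test_that("agreement_report assembles differences with the IAD_M - IAD_auto sign", {
  pairs <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = 4),
    timepoint_ms = rep(seq(0, 300, 100), 3),
    iad_m_mm = 5 + rep(c(0, 0.4, -0.2, 0.1), 3) + rep(c(0, 1, 2), each = 4),
    iad_a_mm = 4 + rep(c(0, 0.4, -0.2, 0.1), 3) + rep(c(0, 1, 2), each = 4),
    iad_s_mm = NA_real_, s_excluded = TRUE
  )
  pairs$iad_s_mm[1:8] <- pairs$iad_a_mm[1:8] + 0.5
  pairs$s_excluded[1:8] <- FALSE
  suppressWarnings({
    rep_a <- agreement_report(pairs, "A")
    rep_s <- agreement_report(pairs, "S")
  })
  expect_equal(rep_a$vc$bias, 1)   # manual reads higher -> positive bias
  expect_equal(rep_s$vc$bias, 0.5, tolerance = 1e-9)
  expect_equal(rep_a$vc$n_pairs, 12L)
  expect_equal(rep_s$vc$n_pairs, 8L)
  expect_equal(rep_s$n_dropped, 4L)
  expect_error(agreement_report(pairs[pairs$participant_id == "a", ], "A"),
               class = "iadct_identifiability_error")
  # no exclusions: S and A see the same n
  no_excl <- pairs
  no_excl$iad_s_mm <- no_excl$iad_a_mm
  no_excl$s_excluded <- FALSE
  suppressWarnings(rep_s2 <- agreement_report(no_excl, "S"))
  expect_equal(rep_s2$vc$n_pairs, suppressWarnings(agreement_report(no_excl, "A"))$vc$n_pairs)
})

test_that("Bland-Altman points are (mean, difference) pairs per row", {
  pairs <- tibble::tibble(participant_id = c("a", "a", "b"),
                          iad_m_mm = c(5, 6, 4),
                          iad_a_mm = c(4, 6, 5),
                          iad_s_mm = c(4.5, NA, NA))
  pts <- bland_altman_points(pairs, "A")
  expect_equal(pts$mean, c(4.5, 6, 4.5))
  expect_equal(pts$difference, c(1, 0, -1))
  expect_equal(nrow(bland_altman_points(pairs, "S")), 1)
  # with zero between-variance the report bias equals the plain mean difference
  d <- simulate_differences(6, 30, 0.8, 0, 1, seed = 506)
  pr <- tibble::tibble(participant_id = d$participant_id,
                       iad_m_mm = 5 + d$difference, iad_a_mm = 5,
                       iad_s_mm = NA_real_, s_excluded = TRUE)
  suppressWarnings(rp <- agreement_report(pr, "A"))
  if (rp$vc$sigma_between == 0) {
    expect_equal(rp$vc$bias, mean(bland_altman_points(pr, "A")$difference),
                 tolerance = 1e-8)
  }
})

test_that("parameter recovery: REML means track the generating truth", {
  # Scaled-down replication (40 seeds) of the recovery study; the acceptance
  # suite runs the full 200-seed version.
  truth <- c(mu = 1.52, sigma_b = 0.73, sigma_w = 1.45)
  est <- t(vapply(seq_len(40), function(s) {
    d <- simulate_differences(12, 47, truth["mu"], truth["sigma_b"],
                              truth["sigma_w"], seed = 600 + s)
    vc <- suppressWarnings(fit_variance_components(d))
    c(vc$bias, vc$sigma_between, vc$sigma_within)
  }, numeric(3)))
  means <- colMeans(est)
  expect_equal(means[1], unname(truth["mu"]), tolerance = 0.10)
  expect_equal(means[2], unname(truth["sigma_b"]), tolerance = 0.10)
  expect_equal(means[3], unname(truth["sigma_w"]), tolerance = 0.03)
})
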