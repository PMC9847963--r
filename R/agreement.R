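#' Paired differences between measurement methods
#'
#' Builds the difference series the agreement model is fit to, with the sign
#' convention `d = IAD_M - IAD_automated`, so a positive bias means the
#' automated estimate reads lower than the manual one.
#'
#' @param pairs A paired-measurement table from [pair_timepoints()] (columns
#'   `participant_id`, `iad_m_mm`, `iad_a_mm`, `iad_s_mm`).
#' @param comparison `"A"` (minimum-over-slices automated vs manual) or
#'   `"S"` (same-slice automated vs manual). For `"S"`, rows whose IAD_S was
#'   excluded are dropped; the count is kept in attribute `n_dropped`.
#' @return A tibble with columns `participant_id`, `difference` (mm).
#' @export
paired_differences <- function(pairs, comparison = c("A", "S")) {
  comparison <- match.arg(comparison)
  pairs <- tibble::as_tibble(pairs)
  check_schema(pairs, c("participant_id", "iad_m_mm",
                        if (comparison == "A") "iad_a_mm" else "iad_s_mm"),
               "`pairs`")
  other <- if (comparison == "A") pairs$iad_a_mm else pairs$iad_s_mm
  keep <- !is.na(other) & !is.na(pairs$iad_m_mm)
  out <- tibble::tibble(
    participant_id = as.character(pairs$participant_id[keep]),
    difference = pairs$iad_m_mm[keep] - other[keep]
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Variance components of repeated paired differences
#'
#' Constructs (or prints) the decomposition used by the modified
#' Bland-Altman analysis: a fixed mean bias plus a between-participant SD
#' and a within-participant (residual) SD, with
#' `total_sd = sqrt(sigma_between^2 + sigma_within^2)`.
#'
#' @param bias Mean of the paired differences, mm.
#' @param sigma_between Between-participant SD, mm.
#' @param sigma_within Within-participant (residual) SD, mm.
#' @param n_pairs,n_participants Sample sizes (optional bookkeeping).
#' @return An object of class `variance_components`.
#' @seealso [fit_variance_components()] to estimate these from data.
#' @export
variance_components <- function(bias, sigma_between, sigma_within,
                                n_pairs = NA_integer_,
                                n_participants = NA_integer_) {
  if (!is.finite(bias)) abort_validation("`bias` must be finite.")
  if (sigma_between < 0 || sigma_within < 0) {
    abort_validation("Standard deviations must be non-negative.")
  }
  structure(list(bias = bias,
                 sigma_between = sigma_between,
                 sigma_within = sigma_within,
                 total_sd = sqrt(sigma_between^2 + sigma_within^2),
                 n_pairs = n_pairs, n_participants = n_participants,
                 method = "given", truncated = FALSE, converged = TRUE),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 2, ...) {
  cat("Variance components of paired differences\n")
  cat(sprintf("  n pairs / participants : %s / %s\n", x$n_pairs, x$n_participants))
  cat(sprintf("  mean bias (mm)         : %.*f\n", digits, x$bias))
  cat(sprintf("  within-participant SD  : %.*f\n", digits, x$sigma_within))
  cat(sprintf("  between-participant SD : %.*f\n", digits, x$sigma_between))
  cat(sprintf("  total SD               : %.*f\n", digits, x$total_sd))
  if (isTRUE(x$truncated)) cat("  (between-participant variance truncated at 0)\n")
  invisible(x)
}

# Restricted -2 log-likelihood (up to an additive constant) of the one-way
# random-intercept model d_ij = mu + b_i + e_ij, written on group summaries.
# Valid at tau = 0.
neg2_rll <- function(tau, sig2, ni, ybar, ssw) {
  N <- sum(ni); k <- length(ni)
  v <- sig2 + ni * tau
  w <- ni / v
  mu <- sum(w * ybar) / sum(w)
  (N - k) * log(sig2) + sum(log(v)) + log(sum(w)) +
    ssw / sig2 + sum(ni * (ybar - mu)^2 / v)
}

#' Fit the one-way random-intercept model to paired differences
#'
#' Estimates the mean bias and the between/within variance components of
#' repeated paired differences, `d_ij = mu + b_i + e_ij` with
#' `b_i ~ N(0, sigma_between^2)` and `e_ij ~ N(0, sigma_within^2)`, where
#' `i` indexes participants. This is the model behind the modified
#' Bland-Altman analysis for repeated measures: treating every difference as
#' independent would understate the participant-level structure.
#'
#' Two estimators are provided. `"reml"` (the default) maximizes the
#' restricted likelihood over the two variance components on the
#' log-variance scale, profiling out the mean; optimization is multi-start
#' from the moments estimate with convergence tolerance `1e-8`, and the
#' `sigma_between = 0` boundary is checked explicitly (negative components
#' are never returned). `"moments"` is the ANOVA-type estimator with the
#' unbalanced-design correction,
#' `sigma_between^2 = (MSB - MSW) / c0` with
#' `c0 = (N - sum(n_i^2)/N) / (k - 1)`, truncated at zero; it serves as an
#' independent cross-check and coincides with REML on balanced designs with
#' interior solutions.
#'
#' @param data A tibble from [paired_differences()] (columns
#'   `participant_id`, `difference`), requiring at least two participants
#'   with at least one difference each.
#' @param method `"reml"` or `"moments"`.
#' @return A [variance_components()] object; `bias` is the GLS mean under
#'   REML and the arithmetic mean under `"moments"`. Fields `truncated` and
#'   `converged` record boundary handling.
#' @examples
#' d <- tibble::tibble(participant_id = rep(c("a", "b"), each = 2),
#'                     difference = c(1, 1, 3, 3))
#' fit_variance_components(d)  # bias 2, sigma_w 0, sigma_b sqrt(2)
#' @export
fit_variance_components <- function(data, method = c("reml", "moments")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  check_schema(data, c("participant_id", "difference"), "`data`")
  d <- data$difference
  if (!length(d) || any(!is.finite(d))) {
    abort_validation("`difference` must be non-empty and finite.")
  }
  pid <- factor(data$participant_id)
  k <- nlevels(pid)
  N <- length(d)
  if (k < 2) {
    abort_identifiability(
      "Between-participant variance is unidentifiable with a single participant.")
  }
  ni <- as.numeric(tabulate(pid))
  ybar <- as.numeric(tapply(d, pid, mean))
  grand <- mean(d)
  ssw <- sum((d - ybar[as.integer(pid)])^2)
  ssb <- sum(ni * (ybar - grand)^2)

  finish <- function(bias, tau, sig2, truncated, converged = TRUE) {
    vc <- variance_components(bias, sqrt(max(0, tau)), sqrt(max(0, sig2)),
                              n_pairs = N, n_participants = k)
    vc$method <- method
    vc$truncated <- truncated
    vc$converged <- converged
    vc
  }

  # Degenerate data: no variation at all.
  if (ssw + ssb < 1e-12 * max(1, grand^2)) {
    warn_iadct("All differences are identical; both variance components are 0.",
               class = "iadct_degenerate_fit")
    return(finish(grand, 0, 0, truncated = FALSE))
  }

  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  c0 <- (N - sum(ni^2) / N) / (k - 1)
  tau_mom_raw <- (msb - msw) / c0
  tau_mom <- max(0, tau_mom_raw)

  if (method == "moments") {
    if (tau_mom_raw < 0) {
      warn_iadct("Moments between-participant variance was negative; truncated at 0.",
                 class = "iadct_truncated_component")
    }
    return(finish(grand, tau_mom, msw, truncated = tau_mom_raw < 0))
  }

  # REML. Perfect within-participant agreement: the residual variance is 0
  # and the restricted likelihood degenerates; fit the between component on
  # the participant means directly.
  if (ssw < 1e-12 * max(1, msb)) {
    tau0 <- sum((ybar - mean(ybar))^2) / (k - 1)
    return(finish(mean(ybar), tau0, 0, truncated = FALSE))
  }

  obj <- function(par) neg2_rll(exp(par[1]), exp(par[2]), ni, ybar, ssw)
  starts <- list(
    c(log(max(tau_mom, 1e-3 * msw)), log(msw)),
    c(log(max(tau_mom, msw) * 10), log(msw)),
    c(log(1e-6 * msw), log(msw))
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, obj, control = list(rel.tol = 1e-12, abs.tol = 0,
                                           x.tol = 1e-12, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  # Boundary profile at tau = 0 (iid model): closed-form REML residual.
  sig2_b0 <- (ssw + ssb) / (N - 1)
  obj_b0 <- neg2_rll(0, sig2_b0, ni, ybar, ssw)

  if (is.null(best) || obj_b0 <= best$objective + 1e-8) {
    truncated <- !is.null(best) # landed on / preferred the boundary
    tau <- 0; sig2 <- sig2_b0
    converged <- TRUE
    if (truncated) {
      warn_iadct("REML between-participant variance truncated at 0.",
                 class = "iadct_truncated_component")
    }
  } else {
    tau <- exp(best$par[1]); sig2 <- exp(best$par[2])
    truncated <- FALSE
    converged <- best$convergence == 0
    if (tau < 1e-10 * sig2) { # optimizer drifted to the boundary
      tau <- 0; sig2 <- sig2_b0; truncated <- TRUE
    }
  }
  v <- sig2 + ni * tau
  w <- ni / v
  finish(sum(w * ybar) / sum(w), tau, sig2, truncated, converged)
}

#' 95% limits of agreement from variance components
#'
#' `bias +/- multiplier * total_sd`, unrounded; the conventional multiplier
#' is the normal quantile 1.96. Reporting layers round the limits to one
#' decimal place.
#'
#' @param vc A [variance_components()] object.
#' @param multiplier Half-width multiplier (default 1.96).
#' @return Named numeric vector `c(lower, upper)` in mm.
#' @examples
#' vc <- variance_components(1.52, 0.73, 1.45)
#' round(limits_of_agreement(vc), 1)  # -1.7, 4.7
#' @export
limits_of_agreement <- function(vc, multiplier = 1.96) {
  stopifnot(inherits(vc, "variance_components"))
  half <- multiplier * vc$total_sd
  c(lower = vc$bias - half, upper = vc$bias + half)
}

#' Repeated-measures Bland-Altman agreement report
#'
#' End-to-end agreement analysis for one method comparison: builds the
#' paired differences (`d = IAD_M - IAD_automated`), fits the
#' variance-components model, and attaches the 95% limits of agreement.
#'
#' @inheritParams paired_differences
#' @param method Estimator passed to [fit_variance_components()].
#' @param multiplier Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `agreement_report`: the fitted
#'   [variance_components()] plus `loa_lower`, `loa_upper`, the comparison
#'   label, and the count of rows dropped by IAD_S exclusions.
#' @export
agreement_report <- function(pairs, comparison = c("A", "S"),
                             method = c("reml", "moments"),
                             multiplier = 1.96) {
  comparison <- match.arg(comparison)
  method <- match.arg(method)
  diffs <- paired_differences(pairs, comparison)
  if (!nrow(diffs)) {
    abort_validation(sprintf(
      "No usable paired differences for comparison '%s' after filtering.", comparison))
  }
  vc <- fit_variance_components(diffs, method = method)
  loa <- limits_of_agreement(vc, multiplier)
  structure(list(comparison = comparison, vc = vc,
                 loa_lower = unname(loa["lower"]),
                 loa_upper = unname(loa["upper"]),
                 multiplier = multiplier,
                 n_dropped = attr(diffs, "n_dropped")),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  lab <- if (x$comparison == "A") "IAD_A vs IAD_M" else "IAD_S vs IAD_M"
  cat(sprintf("Bland-Altman comparison (%s), repeated measures\n", lab))
  cat(sprintf("  Number of paired measurements      %d\n", x$vc$n_pairs))
  cat(sprintf("  Mean bias (mm)                     %.2f\n", x$vc$bias))
  cat(sprintf("  95%% limits of agreement (mm)       %.1f to %.1f\n",
              x$loa_lower, x$loa_upper))
  cat(sprintf("  Within participant SD (mm)         %.2f\n", x$vc$sigma_within))
  cat(sprintf("  Between participant SD (mm)        %.2f\n", x$vc$sigma_between))
  cat(sprintf("  Total SD (mm)                      %.1f\n", x$vc$total_sd))
  if (x$n_dropped > 0) {
    cat(sprintf("  (%d rows without IAD_%s dropped)\n", x$n_dropped, x$comparison))
  }
  invisible(x)
}

#' Bland-Altman plot coordinates
#'
#' Per paired measurement: the mean of the two methods on the x axis and
#' their difference (`IAD_M - other`) on the y axis, keyed by participant so
#' plots can encode the repeated-measures structure.
#'
#' @inheritParams paired_differences
#' @return A tibble with `participant_id`, `mean`, `difference` (mm).
#' @export
bland_altman_points <- function(pairs, comparison = c("A", "S")) {
  comparison <- match.arg(comparison)
  pairs <- tibble::as_tibble(pairs)
  other <- if (comparison == "A") pairs$iad_a_mm else pairs$iad_s_mm
  keep <- !is.na(other) & !is.na(pairs$iad_m_mm)
  tibble::tibble(
    participant_id = as.character(pairs$participant_id[keep]),
    mean = (pairs$iad_m_mm[keep] + other[keep]) / 2,
    difference = pairs$iad_m_mm[keep] - other[keep]
  )
}

#' Simulate paired differences from the one-way random-intercept model
#'
#' Draws `d_ij = mu + b_i + e_ij` directly at the statistical-model level:
#' the workhorse for parameter-recovery studies of
#' [fit_variance_components()].
#'
#' @param n_participants Number of participants (groups).
#' @param n_timepoints Differences per participant.
#' @param mu True mean bias, mm.
#' @param sigma_b True between-participant SD, mm.
#' @param sigma_w True within-participant SD, mm.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @return A tibble with `participant_id`, `difference`.
#' @export
simulate_differences <- function(n_participants, n_timepoints, mu,
                                 sigma_b, sigma_w, seed = NULL) {
  stopifnot(is_count(n_participants), is_count(n_timepoints),
            sigma_b >= 0, sigma_w >= 0)
  with_seed(seed, {
    b <- stats::rnorm(n_participants, 0, sigma_b)
    tibble::tibble(
      participant_id = rep(sprintf("P%02d", seq_len(n_participants)),
                           each = n_timepoints),
      difference = mu + rep(b, each = n_timepoints) +
        stats::rnorm(n_participants * n_timepoints, 0, sigma_w)
    )
  })
}
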