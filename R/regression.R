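#' Mixed-effects regression of manual on automated IAD
#'
#' Fits `IAD_M ~ IAD_A` (or `IAD_S`) with per-participant random slopes and
#' intercepts, the repeated-measures analogue of the scatter-plot regression
#' line. When the full random-slopes model fails to converge (or errors,
#' e.g. on noiseless data with zero residual variance), the fit falls back
#' to random intercepts only, and from there to an ordinary fixed-effects
#' line; the level actually used is recorded and flagged.
#'
#' @inheritParams paired_differences
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept` (fixed effects), `ranef` (tibble of per-participant
#'   intercept/slope deviations, zero rows for the fixed fallback), `model`
#'   (`"slopes"`, `"intercepts"` or `"fixed"`), `fallback` (logical),
#'   `converged`, `singular` and any collected fit messages.
#' @export
mixed_regression <- function(pairs, comparison = c("A", "S")) {
  comparison <- match.arg(comparison)
  pairs <- tibble::as_tibble(pairs)
  other_col <- if (comparison == "A") "iad_a_mm" else "iad_s_mm"
  check_schema(pairs, c("participant_id", "iad_m_mm", other_col), "`pairs`")
  keep <- !is.na(pairs[[other_col]]) & !is.na(pairs$iad_m_mm)
  df <- data.frame(y = pairs$iad_m_mm[keep],
                   x = pairs[[other_col]][keep],
                   pid = factor(pairs$participant_id[keep]))
  if (nlevels(df$pid) < 2) {
    abort_identifiability("Mixed regression needs at least two participants.")
  }
  if (stats::sd(df$x) < 1e-12) {
    abort_validation("Degenerate predictor: the automated IAD has zero variance.")
  }

  notes <- character()
  quiet_lmer <- function(formula) {
    fit <- NULL
    tryCatch(
      withCallingHandlers(
        fit <- lme4::lmer(formula, data = df, REML = TRUE),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          notes <<- c(notes, conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      ),
      error = function(e) notes <<- c(notes, conditionMessage(e)))
    fit
  }
  lmer_converged <- function(fit) {
    cc <- fit@optinfo$conv$lme4
    is.null(cc$code) || cc$code >= 0 && length(cc$messages) == 0
  }

  fit <- quiet_lmer(y ~ x + (1 + x | pid))
  model <- "slopes"
  if (is.null(fit) || !lmer_converged(fit)) {
    fit <- quiet_lmer(y ~ x + (1 | pid))
    model <- "intercepts"
  }
  if (!is.null(fit) && model == "intercepts" && !lmer_converged(fit)) fit <- NULL

  if (is.null(fit)) {
    lm_fit <- stats::lm(y ~ x, data = df)
    res <- list(slope = unname(stats::coef(lm_fit)["x"]),
                intercept = unname(stats::coef(lm_fit)["(Intercept)"]),
                ranef = tibble::tibble(participant_id = character(),
                                       intercept_dev = numeric(),
                                       slope_dev = numeric()),
                model = "fixed", fallback = TRUE,
                converged = TRUE, singular = FALSE, notes = notes)
  } else {
    fe <- lme4::fixef(fit)
    re <- as.data.frame(lme4::ranef(fit)$pid)
    res <- list(
      slope = unname(fe["x"]),
      intercept = unname(fe["(Intercept)"]),
      ranef = tibble::tibble(
        participant_id = rownames(re),
        intercept_dev = re[["(Intercept)"]],
        slope_dev = if ("x" %in% names(re)) re[["x"]] else rep(0, nrow(re))
      ),
      model = model, fallback = model != "slopes",
      converged = lmer_converged(fit),
      singular = lme4::isSingular(fit), notes = notes)
  }
  res$n <- nrow(df)
  res$comparison <- comparison
  class(res) <- "regression_fit"
  res
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Mixed regression IAD_M ~ IAD_%s (n = %d)\n", x$comparison, x$n))
  cat(sprintf("  fixed slope     %.3f\n  fixed intercept %.3f\n", x$slope, x$intercept))
  cat(sprintf("  random effects  %s%s%s\n", x$model,
              if (x$fallback) " (fallback)" else "",
              if (x$singular) " [singular]" else ""))
  invisible(x)
}
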