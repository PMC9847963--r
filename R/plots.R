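#' Agreement plots
#'
#' Publication-style figures for one method comparison: a Bland-Altman plot
#' (differences against means with the bias and 95% limits of agreement
#' overlaid) and a paired scatter plot (manual against automated estimates
#' with the identity line and the mixed-regression fixed-effect line).
#' Both require ggplot2.
#'
#' @inheritParams paired_differences
#' @param report Optional [agreement_report()] for the same comparison
#'   (computed if omitted).
#' @return A ggplot object.
#' @name agreement_plots
NULL

#' @rdname agreement_plots
#' @export
plot_bland_altman <- function(pairs, comparison = c("A", "S"), report = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_validation("plot_bland_altman() requires the ggplot2 package.")
  }
  comparison <- match.arg(comparison)
  if (is.null(report)) report <- agreement_report(pairs, comparison)
  pts <- bland_altman_points(pairs, comparison)
  lab <- if (comparison == "A") "IAD_A" else "IAD_S"
  ggplot2::ggplot(pts, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(ggplot2::aes(colour = participant_id),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = report$vc$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(report$loa_lower, report$loa_upper),
                        linetype = "dotted") +
    ggplot2::labs(x = sprintf("Mean of IAD_M and %s (mm)", lab),
                  y = sprintf("IAD_M - %s (mm)", lab)) +
    ggplot2::theme_minimal()
}

#' @rdname agreement_plots
#' @export
plot_paired_scatter <- function(pairs, comparison = c("A", "S")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_validation("plot_paired_scatter() requires the ggplot2 package.")
  }
  comparison <- match.arg(comparison)
  pairs <- tibble::as_tibble(pairs)
  other <- if (comparison == "A") pairs$iad_a_mm else pairs$iad_s_mm
  keep <- !is.na(other) & !is.na(pairs$iad_m_mm)
  df <- tibble::tibble(x = other[keep], y = pairs$iad_m_mm[keep],
                       participant_id = pairs$participant_id[keep])
  fit <- mixed_regression(pairs, comparison)
  lab <- if (comparison == "A") "IAD_A" else "IAD_S"
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(ggplot2::aes(colour = participant_id),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(x = sprintf("%s (mm)", lab), y = "IAD_M (mm)") +
    ggplot2::theme_minimal()
}
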