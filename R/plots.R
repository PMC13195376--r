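#' Bland-Altman plot of tract-level agreement
#'
#' Per-tract difference (EHR minus reference) against the mean of the two
#' estimates, with the mean difference and the 1.96-SD limits of
#' agreement.
#'
#' @param object A [concordance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tractprev_concordance <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(
    object$tracts,
    ggplot2::aes(x = .data$mean_pair, y = .data$difference)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = s$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(s$loa_low, s$loa_high),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Mean of EHR and reference prevalence (%)",
      y = "EHR - reference (percentage points)",
      title = "Bland-Altman agreement across census tracts"
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a tract covariate model
#'
#' @param object A [fit_prevalence_model()] result.
#' @param ... Unused.
#' @return A ggplot object (estimates with 95% CIs, intercept omitted).
#' @exportS3Method ggplot2::autoplot
autoplot.tract_model <- function(object, ...) {
  td <- tidy.tract_model(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(
    td,
    ggplot2::aes(x = .data$estimate, y = stats::reorder(.data$term, .data$estimate))
  ) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::labs(
      x = "Coefficient (percentage points of prevalence)", y = NULL,
      title = paste(
        "Tract covariate associations",
        if (!is.null(object$condition)) paste0("- ", object$condition)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of stratum coverage ratios
#'
#' @param x A [ratio_table()] result.
#' @param stratum Column to label rows by (first `by` column if omitted).
#' @return A ggplot object with a reference line at ratio 1.
#' @export
plot_ratio_table <- function(x, stratum = NULL) {
  if (is.null(stratum)) {
    stratum <- setdiff(
      names(x), c("ehr_n", "census_n", "ratio", "ratio_display", "undefined")
    )[1]
  }
  ggplot2::ggplot(
    x[!x$undefined, ],
    ggplot2::aes(x = .data$ratio, y = .data[[stratum]])
  ) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "EHR-to-census ratio", y = NULL,
      title = "Population coverage by stratum"
    ) +
    ggplot2::theme_minimal()
}
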