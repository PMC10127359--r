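# Quick-look graphics: one plot_*/autoplot per result type.

#' Scatter of desiccation resistance against each covariate
#'
#' Faceted quick-look at the raw relationships the models formalize:
#' desiccation resistance against log body mass, water loss rate, water loss
#' tolerance and fractional water content, coloured by nesting guild.
#'
#' @param traits Trait table from [derive_traits()].
#' @return A ggplot object.
#' @export
plot_desiccation <- function(traits) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(traits),
    cols = c(
      "log_body_mass", "water_loss_rate",
      "water_loss_tolerance", "fractional_water_content"
    ),
    names_to = "covariate", values_to = "value"
  )
  ggplot2::ggplot(
    dplyr::filter(long, !is.na(.data$value)),
    ggplot2::aes(.data$value, .data$desiccation_resistance,
      colour = .data$nesting_strategy
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "Desiccation resistance (survival / horizon)",
      colour = "Nesting guild"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn signal_test Null distribution of the contrast variance with
#'   the observed value marked.
#' @param object A `signal_test` result.
#' @param ... Unused.
#' @method autoplot signal_test
#' @export
autoplot.signal_test <- function(object, ...) {
  ggplot2::ggplot(
    tibble::tibble(null = object$null_variances),
    ggplot2::aes(.data$null)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_variance, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf(
        "Tip-shuffle null for %s (p = %.3g)", object$trait, object$p_value
      ),
      x = "Contrast variance under tip shuffles", y = "Count"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_glm Coefficient forest plot with 95% Wald intervals.
#' @param object A `wb_fit`.
#' @param ... Unused.
#' @method autoplot wb_fit
#' @export
autoplot.wb_fit <- function(object, ...) {
  tab <- tidy(object)
  tab <- tab[tab$term != "(Intercept)", ]
  ggplot2::ggplot(tab, ggplot2::aes(.data$estimate, stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error
    )) +
    ggplot2::labs(x = "Estimate (logit scale, 95% Wald interval)", y = NULL) +
    ggplot2::theme_minimal()
}
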