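#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a growth dataset
#'
#' Growth rate against the (prepared) lag-1 density predictor, one panel per
#' site, with a least-squares guide line.
#'
#' @param object A `growth_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_dataset <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag1, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "density in previous year (prepared scale)",
                  y = "growth rate R") +
    ggplot2::theme_minimal()
}

#' Plot a ranked candidate table
#'
#' Akaike weights of the candidate models, ordered by rank, with the
#' plausibility cutoff annotated.
#'
#' @param object A `candidate_table`.
#' @param plausible_cut AICc-difference cutoff used to flag plausible models.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_table <- function(object, plausible_cut = 2, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  df$plausible <- df$delta_aicc < plausible_cut
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model,
                                   fill = .data$plausible)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model-averaged coefficients
#'
#' Conditional model-averaged estimates with their confidence intervals.
#'
#' @param object An `averaged_coefficients` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.averaged_coefficients <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "standardized estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Partial-effect plot for a fitted model
#'
#' Shows the partial relationship between the growth rate and one model term:
#' the term's contribution plus residuals against the term's column, with the
#' fitted partial slope.
#'
#' @param fit A `dd_fit`.
#' @param design The `dd_design` it was fitted to.
#' @param term Term to display (e.g. `"L1"` or `"TIME"`).
#' @return A ggplot object.
#' @export
plot_partial_effect <- function(fit, design, term) {
  if (!term %in% colnames(design$X)) {
    stop("term '", term, "' is not in the fitted design", call. = FALSE)
  }
  b <- fit$coefficients$estimate[fit$coefficients$term == term]
  x <- design$X[, term]
  partial <- b * x + fit$residuals
  df <- tibble::tibble(x = x, partial = partial)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$partial)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = b) +
    ggplot2::labs(x = paste(term, "(standardized)"),
                  y = "partial growth rate") +
    ggplot2::theme_minimal()
}
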