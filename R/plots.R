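#' Plot a model-averaged monthly survival series
#'
#' Points and 95% intervals per interval, coloured by treatment group — the
#' standard display for an exclusion experiment's survival contrast.
#'
#' @param surv a [survival_series] tibble.
#' @return A ggplot object.
#' @export
plot_survival <- function(surv) {
  ggplot2::ggplot(surv, ggplot2::aes(x = .data$interval, y = .data$estimate,
                                     colour = .data$treatment)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "Interval between sessions",
                  y = "Monthly apparent survival", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot model-averaged relative survival
#'
#' Treatment/control survival ratio per interval with 95% intervals and the
#' null line at 1.
#'
#' @param rels a [relative_survival] tibble.
#' @return A ggplot object.
#' @export
plot_relative_survival <- function(rels) {
  ggplot2::ggplot(rels, ggplot2::aes(x = .data$interval, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Interval between sessions",
                  y = "Relative survival (treatment / control)") +
    ggplot2::theme_minimal()
}

#' Plot model-averaged population size
#'
#' Abundance per session and plot with 95% intervals, faceted by location
#' when plot labels follow the `location.role` convention.
#'
#' @param abund the `abundance` tibble from [abundance_series].
#' @return A ggplot object.
#' @export
plot_abundance <- function(abund) {
  ggplot2::ggplot(abund, ggplot2::aes(x = .data$session, y = .data$estimate,
                                      colour = .data$plot)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "Session", y = "Estimated population size",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.latent_class_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$session, y = .data$mean_mass,
                               colour = factor(.data$class),
                               linetype = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Session", y = "Mean body mass (g)",
                  colour = "Class", linetype = "Sex") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gof_result <- function(object, ...) {
  df <- tibble::tibble(deviance = object$deviance_boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$deviance_obs, colour = "red") +
    ggplot2::labs(x = "Bootstrap deviance", y = "Count") +
    ggplot2::theme_minimal()
}
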