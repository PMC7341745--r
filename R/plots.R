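# ggplot2 displays for the package's result objects.

#' @export
autoplot.melt_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$temperature_C,
                               y = .data$fluorescence,
                               group = .data$replicate)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "temperature (°C)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(temperature_C = seq(min(d$temperature_C),
                                     max(d$temperature_C), length.out = 200))
  grid$fluorescence <- predict(object$fit,
                               newdata = list(Tv = grid$temperature_C))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_C,
                                  y = .data$fluorescence)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = 2) +
    ggplot2::labs(x = "temperature (°C)", y = "fluorescence (a.u.)",
                  subtitle = sprintf("T1/2 = %.2f °C", object$t_half)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sequence_archive <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$energy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank", y = "folding energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.filter_report <- function(object, ...) {
  d <- object$stages
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.2,
                       size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "surviving sequences") +
    ggplot2::theme_minimal()
}
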