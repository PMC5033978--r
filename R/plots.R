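#' Plot a fitted decay curve over its series
#'
#' @param object A `decay_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$x, y = object$y,
                        fitted = predict(object))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8,
                       colour = "#2166ac") +
    ggplot2::labs(x = "Error-clamp trial within block",
                  y = expression(Force~at~peak~velocity~(N%.%s%.%m^-1)),
                  subtitle = sprintf("y = %.2f e^(%.3f x) + %.2f,  r² = %.3f",
                                     object$a, object$b, object$c, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap and permutation difference distributions
#'
#' Histograms of the permutation differences per parameter with the mean
#' bootstrap difference overlaid — the quantities from which the comparison
#' p-values are read.
#'
#' @param object A `decay_comparison`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_comparison <- function(object, ...) {
  perm <- tidyr::pivot_longer(object$perm, dplyr::everything(),
                              names_to = "parameter", values_to = "diff")
  md <- tibble::tibble(parameter = names(object$mean_diff),
                       mean_diff = unname(object$mean_diff))
  ggplot2::ggplot(perm, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = md, ggplot2::aes(xintercept = .data$mean_diff),
                        colour = "#b2182b", linewidth = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = sprintf("Difference (%s - %s)", object$pair[1], object$pair[2]),
                  y = "Permutation count",
                  subtitle = sprintf("p: %s",
                                     paste(names(object$p),
                                           signif(object$p, 3),
                                           sep = " = ", collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot the group-average error-clamp decay series
#'
#' The across-participants mean of the per-participant 30-trial decay series,
#' by feedback group.
#'
#' @param series An [ec_series()] tibble.
#' @return A ggplot.
#' @export
plot_ec_decay <- function(series) {
  avg <- series |>
    dplyr::group_by(.data$group, .data$position) |>
    dplyr::summarise(force = mean(.data$force), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$position, y = .data$force,
                                    colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Error-clamp trial within block",
                  y = expression(Force~at~peak~velocity~(N%.%s%.%m^-1)),
                  colour = "Feedback") +
    ggplot2::theme_minimal()
}
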