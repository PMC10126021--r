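#' Plot a fitted relational event model
#'
#' Dot-and-whisker plot of coefficient estimates with 95% Wald intervals.
#'
#' @param object A `rem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rem_fit
#' @export
autoplot.rem_fit <- function(object, ...) {
  tab <- tidy(object)
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(
      x = "coefficient (log rate)", y = NULL,
      title = paste0("Relational event model (", object$kind, " likelihood)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a moving-window coefficient trajectory
#'
#' One panel per effect: the per-window estimate with a 95% Wald ribbon
#' against the window midpoint (in days).
#'
#' @param object A `rem_window_trajectory`.
#' @param terms Optional subset of effect names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rem_window_trajectory
#' @export
autoplot.rem_window_trajectory <- function(object, terms = NULL, ...) {
  est <- object$estimates
  if (!is.null(terms)) {
    est <- est[est$term %in% terms, ]
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$label, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$estimate - 1.96 * .data$std.error,
        ymax = .data$estimate + 1.96 * .data$std.error
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "window midpoint (day)", y = "coefficient (log rate)") +
    ggplot2::theme_minimal()
}
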