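# ggplot2 methods for the result types.

#' Plot a length profile
#'
#' Mean syllable length against word length in syllables, optionally with
#' the exact memoryless-source curve `a/m + b` overlaid for comparison.
#'
#' @param object A length profile tibble (class `"menz_profile"`).
#' @param null_curve Optional `"null_curve"` object to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot menz_profile
#' @export
autoplot.menz_profile <- function(object, null_curve = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$mean_y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "word length m (syllables)",
      y = "mean syllable length (graphemes)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(null_curve)) {
    grid <- tibble(
      m = seq(min(object$m), max(object$m), length.out = 200)
    )
    grid$y <- null_curve$a / grid$m + null_curve$b
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$m, y = .data$y),
      linetype = "dashed"
    )
  }
  p
}

#' Plot a Menzerath-Altmann fit
#'
#' Profile bins as points with the fitted curve; the extremum, when the fit
#' lands in the inverted regime, is marked with a vertical line.
#'
#' @param object A `"mal_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mal_fit
#' @export
autoplot.mal_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(m = seq(min(dat$m), max(dat$m), length.out = 200))
  grid$y <- predict(object, grid$m)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$m, y = .data$mean_y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$m, y = .data$y),
                       colour = "red") +
    ggplot2::labs(
      x = "word length m (syllables)",
      y = "mean syllable length (graphemes)",
      title = sprintf(
        "y = %.3g m^%.3g exp(%.3g m), R² = %.3f",
        object$alpha, object$beta, -object$gamma, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$extremum_m)) {
    p <- p + ggplot2::geom_vline(xintercept = object$extremum_m,
                                 linetype = "dotted")
  }
  p
}

#' Plot a positional syllable-length profile
#'
#' Mean syllable length against standardized position `x`, one line per
#' word length `m`; the monosyllable mean sits alone at `x = 0.5`.
#'
#' @param object A `"menz_positions"` tibble from [positional_means()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot menz_positions
#' @export
autoplot.menz_positions <- function(object, ...) {
  multi <- dplyr::filter(object, .data$m > 1)
  mono <- dplyr::filter(object, .data$m == 1)
  p <- ggplot2::ggplot(
    multi,
    ggplot2::aes(x = .data$x, y = .data$mean_length,
                 colour = factor(.data$m), group = .data$m)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "standardized position x",
      y = "mean syllable length (graphemes)",
      colour = "word length m"
    ) +
    ggplot2::theme_minimal()
  if (nrow(mono) > 0) {
    p <- p + ggplot2::geom_point(
      data = mono,
      ggplot2::aes(x = .data$x, y = .data$mean_length),
      inherit.aes = FALSE, colour = "black", size = 3
    )
  }
  p
}
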