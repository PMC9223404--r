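#' Tidy a tension fit
#'
#' Returns one row per estimated coefficient and derived quantity, in
#' broom style.
#'
#' @param x A `tension_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate` and, for unconstrained
#'   fits, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.tension_fit <- function(x, ...) {
  if (!is.null(x$std_errors)) {
    se <- x$std_errors
    tibble(term = se$term, estimate = se$estimate,
           std.error = se$std_error,
           conf.low = se$conf_low, conf.high = se$conf_high,
           kind = se$kind)
  } else {
    tibble(term = names(x$coefficients)[-1],
           estimate = unname(x$coefficients[-1]),
           kind = "coefficient")
  }
}

#' Glance at a tension fit
#'
#' @inheritParams tidy.tension_fit
#' @return One-row tibble with `model`, `n`, `p`, `sigma2`, `AIC`,
#'   `boundary`.
#' @export
glance.tension_fit <- function(x, ...) {
  tibble(model = format(x$spec), n = x$n, p = x$p, sigma2 = x$sigma2,
         AIC = x$aic, boundary = x$boundary)
}

#' @rdname tidy.tension_fit
#' @export
tidy.model_selection <- function(x, ...) x$table

#' @rdname glance.tension_fit
#' @export
glance.model_selection <- function(x, ...) {
  tibble(best = format(x$best), n_candidates = nrow(x$table),
         n_failed = sum(!is.na(x$table$error)))
}

#' @rdname tidy.tension_fit
#' @export
tidy.noise_report <- function(x, ...) x$deviations

#' @rdname glance.tension_fit
#' @export
glance.noise_report <- function(x, ...) {
  tibble(n_rep = nrow(x$correlations) + x$n_failed, n_failed = x$n_failed,
         min_r = x$min_r, median_r = x$median_r,
         max_median_abs_delta_q = max(x$medians$median_abs_delta_q))
}

#' Plot a tissue
#'
#' Draws the junction network, optionally coloured by a per-junction value.
#'
#' @param object A [tissue()].
#' @param colour Optional numeric vector, one value per junction (for
#'   example predicted tensions).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tissue <- function(object, colour = NULL, ...) {
  v <- object$vertices
  seg <- dplyr::mutate(object$junctions,
                       x = v$x[match(.data$v1, v$id)],
                       y = v$y[match(.data$v1, v$id)],
                       xend = v$x[match(.data$v2, v$id)],
                       yend = v$y[match(.data$v2, v$id)])
  p <- if (is.null(colour)) {
    ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                      xend = .data$xend, yend = .data$yend)) +
      ggplot2::geom_segment(linewidth = 0.3)
  } else {
    seg$value <- colour
    ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                      xend = .data$xend, yend = .data$yend,
                                      colour = .data$value)) +
      ggplot2::geom_segment(linewidth = 0.5) +
      ggplot2::scale_colour_viridis_c()
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Plot predicted tension against junction length and orientation
#'
#' The diagnostic view of a fitted tension model: predicted junction
#' tension versus junction length, coloured by orientation class.
#'
#' @param object A `tension_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tension_fit <- function(object, ...) {
  d <- object$predicted_tensions
  d$orientation <- ifelse(abs(sin(d$angle)) < sin(pi / 4), "axial", "transverse")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$tension,
                                  colour = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "junction length", y = "predicted tension") +
    ggplot2::theme_minimal()
}

#' Plot the energy relaxation of a simulation
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot of virtual work against time.
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$energy_trace,
                  ggplot2::aes(x = .data$time, y = .data$U0)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "virtual work U0") +
    ggplot2::theme_minimal()
}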