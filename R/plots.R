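#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cost-effectiveness interval grid
#'
#' Incremental cost per QALY gained (efficiency) against the follow-up
#' interval, with optional willingness-to-pay reference lines.
#'
#' @param object An [interval_grid()] result.
#' @param thresholds Willingness-to-pay lines to draw (USD/QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colocea_grid <- function(object, thresholds = c(5e4, 7.5e4, 1e5), ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$icer)) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Follow-up interval (years)",
      y = "Incremental cost per QALY gained ($/QALY)",
      title = sprintf("Screening at age %s, %s",
                      attr(object, "screen_age"), attr(object, "finding"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot QALY gain against follow-up interval
#'
#' Effectiveness curve: incremental QALYs per 10,000 persons by follow-up
#' interval, the curve the quadratic interpolation optimizes over.
#'
#' @param grid An [interval_grid()] result.
#' @param optimum Optional [optimal_interval()] row to mark.
#' @return A ggplot object.
#' @export
plot_qaly_gain <- function(grid, optimum = NULL) {
  df <- tibble::as_tibble(grid)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$interval,
                                        y = .data$d_qalys * 1e4)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Follow-up interval (years)",
                  y = "QALYs gained per 10,000 persons") +
    ggplot2::theme_minimal()
  if (!is.null(optimum) && is.finite(optimum$interval)) {
    g <- g + ggplot2::geom_vline(xintercept = optimum$interval,
                                 linetype = "dotted", colour = "red")
  }
  g
}

#' Plot a fitted breakpoint survival model
#'
#' Overlays the fitted stage-specific and overall (mixture) survival curves
#' on the fitted data points.
#'
#' @param object A [fit_breakpoint_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  tt <- seq(0, 10, by = 0.1)
  curves <- purrr::map_dfr(object$hazards$stage, function(s) {
    tibble::tibble(stage = s, years_since_dx = tt,
                   survival = crc_survival(object$hazards[object$hazards$stage == s, ], tt))
  })
  overall <- tibble::tibble(
    stage = "overall (mixture)", years_since_dx = tt,
    survival = overall_crc_survival(object$hazards, object$mix, tt)
  )
  pts <- object$overall_curve
  ggplot2::ggplot(dplyr::bind_rows(curves, overall),
                  ggplot2::aes(x = .data$years_since_dx, y = .data$survival,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts, colour = "black",
                        ggplot2::aes(x = .data$years_since_dx, y = .data$survival)) +
    ggplot2::labs(x = "Years since diagnosis", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
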