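#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a bootstrap replicate distribution with its point estimate and percentile
#' interval, the staggered-entry survival curve over the 8-interval annual
#' cycle, the stationary reproductive-state distribution, and the Monte
#' Carlo lambda distribution. `plot_stable_age()` shows a stable age
#' distribution as a bar chart over age classes.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name bearvitals-plots
NULL

#' @rdname bearvitals-plots
#' @export
autoplot.boot_dist <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(value = object$replicates),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$point, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = object$statistic, y = "bootstrap replicates",
                  title = sprintf("%s: %.3f (%.3f-%.3f)", object$statistic,
                                  object$point, object$ci_low, object$ci_high))
}

#' @rdname bearvitals-plots
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- object$interval |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$interval, .by_group = TRUE) |>
    dplyr::mutate(S = cumprod(.data$s_hat)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$S,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "monitoring interval (Apr..Oct, pooled winter)",
                  y = "cumulative survival", colour = "group")
}

#' @rdname bearvitals-plots
#' @export
autoplot.stable_state <- function(object, ...) {
  ggplot2::ggplot(tidy.stable_state(object),
                  ggplot2::aes(x = .data$state, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "reproductive state", y = "stationary proportion")
}

#' @rdname bearvitals-plots
#' @export
autoplot.projection_summary <- function(object, ...) {
  ggplot2::ggplot(object$iterations, ggplot2::aes(x = .data$lambda)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(
      xintercept = object$summary$point[object$summary$quantity == "lambda"],
      linewidth = 0.8
    ) +
    ggplot2::labs(x = expression(lambda), y = "Monte Carlo iterations")
}

#' @rdname bearvitals-plots
#' @param stable_age Named vector from [stable_age_distribution()].
#' @export
plot_stable_age <- function(stable_age, ...) {
  df <- tibble::tibble(age = as.integer(names(stable_age)),
                       proportion = unname(stable_age))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "age (years)", y = "stable proportion")
}
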