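#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for bearvitals objects
#'
#' `tidy()` returns one row per estimated quantity with point estimate and
#' 95% interval; `glance()` returns a one-row model-level summary. These
#' follow the usual broom conventions so results drop straight into dplyr
#' pipelines.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name bearvitals-tidiers
NULL

#' @rdname bearvitals-tidiers
#' @export
tidy.boot_dist <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, estimate = x$point,
    ci_low = x$ci_low, ci_high = x$ci_high,
    B = x$B, n = x$n,
    flags = if (length(x$flags)) paste(x$flags, collapse = ";") else NA_character_
  )
}

#' @rdname bearvitals-tidiers
#' @export
tidy.km_fit <- function(x, ...) x$annual

#' @rdname bearvitals-tidiers
#' @export
tidy.known_fate_model <- function(x, ...) {
  dplyr::transmute(
    x$cells,
    model = x$name, cell = .data$cell,
    estimate = .data$s_annual, ci_low = .data$ci_low, ci_high = .data$ci_high,
    n_intervals = .data$n, n_deaths = .data$deaths
  )
}

#' @rdname bearvitals-tidiers
#' @export
glance.known_fate_model <- function(x, ...) {
  tibble::tibble(model = x$name, k = x$k, loglik = x$loglik,
                 AICc = x$AICc, ess = x$ess)
}

#' @rdname bearvitals-tidiers
#' @export
tidy.transition_matrix <- function(x, ...) {
  idx <- which(permitted_mask(), arr.ind = TRUE)
  tibble::tibble(
    from = REPRO_STATES[idx[, 1]], to = REPRO_STATES[idx[, 2]],
    estimate = x$P[idx],
    count = if (is.null(x$counts)) NA_integer_ else x$counts[idx]
  ) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @rdname bearvitals-tidiers
#' @export
tidy.stable_state <- function(x, ...) {
  tibble::tibble(state = REPRO_STATES, proportion = unname(x$pi))
}

#' @rdname bearvitals-tidiers
#' @export
tidy.projection_summary <- function(x, ...) x$summary

#' @rdname bearvitals-tidiers
#' @export
glance.projection_summary <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    lambda = s$point[s$quantity == "lambda"],
    R0 = s$point[s$quantity == "R0"],
    gen_time = s$point[s$quantity == "gen_time"],
    n_iter = x$n_iter, rejected = x$rejected
  )
}
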