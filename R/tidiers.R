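#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted current-trace model
#'
#' @param x A `glu_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   whether it was `free`, its bounds, and the restart spread (s.d. of the
#'   estimate across optimizer restarts; the package's only uncertainty
#'   surrogate).
#' @export
tidy.glu_fit <- function(x, ...) {
  spread <- rep(NA_real_, length(x$par))
  names(spread) <- names(x$par)
  spread[names(x$restart_spread)] <- x$restart_spread
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    free = names(x$par) %in% x$free,
    lower = unname(x$spec$lower[names(x$par)]),
    upper = unname(x$spec$upper[names(x$par)]),
    restart_spread = unname(spread)
  )
}

#' One-row summary of a fitted current-trace model
#'
#' @param x A `glu_fit`.
#' @param ... Unused.
#' @return A tibble with the objective (mean squared residual, pA²), RMSE,
#'   number of samples, condition, convergence flag and seed.
#' @export
glance.glu_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    rmse = sqrt(x$objective),
    n = nrow(x$data),
    n_free = length(x$free),
    condition = x$condition,
    converged = x$converged,
    seed = x$seed
  )
}

#' Tidy a PSTH sine fit
#'
#' @param x A `psth_sine_fit`.
#' @param ... Unused.
#' @return One-row tibble of the fitted sine parameters.
#' @export
tidy.psth_sine_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude,
    cycles_per_period = x$cycles_per_period,
    phase_deg = x$phase_deg,
    offset = x$offset,
    goodness = x$goodness,
    degenerate = x$degenerate
  )
}

#' Plot a fitted current trace over the data
#'
#' Data, fitted model current and residuals, faceted.
#'
#' @param object A `glu_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glu_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time_ms = object$data$time_ms,
                   current_pA = object$data$current_pA, what = "data"),
    tibble::tibble(time_ms = object$fitted$time_ms,
                   current_pA = object$fitted$current_pA, what = "fit"),
    tibble::tibble(time_ms = object$residuals$time_ms,
                   current_pA = object$residuals$residual_pA,
                   what = "residual")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$current_pA,
                                   color = .data$what)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$what == "residual"), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "current (pA)", color = NULL,
                  title = sprintf("%s fit, RMSE %.2f pA", object$condition,
                                  sqrt(object$objective))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text = ggplot2::element_blank())
}

#' Plot a cycle-folded PSTH with its fitted sine
#'
#' @param object A `glu_psth`.
#' @param fit Optional `psth_sine_fit` to overlay (computed if `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glu_psth <- function(object, fit = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$bin_center_deg, .data$rate_hz)) +
    ggplot2::geom_col(width = attr(object, "bin_deg"), fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(90, 270), linetype = 3) +
    ggplot2::labs(x = "stimulus phase (deg; 90 = peak rate, 270 = slowest)",
                  y = "firing rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (isTRUE(fit)) fit <- fit_sine(object)
  if (inherits(fit, "psth_sine_fit")) {
    curve <- tibble::tibble(bin_center_deg = seq(0, 360, 0.5))
    curve$rate_hz <- predict(fit, curve$bin_center_deg)
    p <- p + ggplot2::geom_line(data = curve, color = "firebrick")
  }
  p
}

#' Plot a steady-state dose–response curve
#'
#' @param dr Output of [dose_response()].
#' @return A ggplot object with a log-scaled concentration axis and the
#'   peak concentration marked.
#' @export
plot_dose_response <- function(dr) {
  ggplot2::ggplot(dr, ggplot2::aes(.data$conc_uM, abs(.data$current_pA))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(dr, "peak_uM"), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "glutamate (uM)", y = "|equilibrium current| (pA)") +
    ggplot2::theme_minimal()
}

#' Plot a sampled trace
#'
#' @param trace Two-column trace tibble (`time_ms` first).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  nm <- names(trace)[2]
  ggplot2::ggplot(trace, ggplot2::aes(.data$time_ms, .data[[nm]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = nm) +
    ggplot2::theme_minimal()
}
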