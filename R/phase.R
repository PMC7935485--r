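#' Map time in the modulated segment to stimulus phase in degrees
#'
#' The instantaneous stimulus rate is `carrier + depth*cos(2*pi*f_mod*t)`,
#' maximal at the start of each modulation cycle.  The convention maps the
#' peak stimulus rate to 90° and the slowest rate to 270°, so
#' `theta(t) = (90 + 360*f_mod*t/1000) mod 360` for `t` in ms measured from
#' the start of the modulated segment.
#'
#' @param t_ms Times in ms from the start of the modulated segment.
#' @param f_mod Modulation frequency, Hz.
#' @return Phase(s) in degrees in `[0, 360)`.
#' @export
stimulus_phase_deg <- function(t_ms, f_mod) {
  (90 + 360 * f_mod * t_ms / 1000) %% 360
}

#' Cycle-folded peristimulus time histogram
#'
#' Spikes recorded during the frequency-modulated segment are folded over
#' modulation cycles, mapped to phase under the 90°/270° convention, binned,
#' and normalized to a firing rate in spikes/s.  Spikes falling in
#' negative-rate (silent) stimulus intervals are retained and folded like
#' any others.
#'
#' @param spike_times Spike times in ms from the start of the modulated
#'   segment: a numeric vector, or a tibble with columns `sweep` and
#'   `time_ms` (multiple sweeps).
#' @param spec A [stimulus_spec()] (provides `f_mod` and `modulated_s`).
#' @param bin_deg Bin width in degrees; must divide 360 (default 10).
#' @param n_sweeps Number of sweeps folded together (inferred from a
#'   `sweep` column if present; default 1).
#' @return A tibble of class `glu_psth` with `bin_center_deg`, `count`,
#'   `rate_hz`, and attributes `f_mod`, `n_cycles`, `n_sweeps`, `bin_deg`.
#' @export
build_psth <- function(spike_times, spec, bin_deg = 10, n_sweeps = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (is.data.frame(spike_times)) {
    if (is.null(n_sweeps)) n_sweeps <- length(unique(spike_times$sweep))
    spike_times <- spike_times$time_ms
  }
  if (is.null(n_sweeps)) n_sweeps <- 1
  if (abs(360 %% bin_deg) > 1e-9) {
    stop("bin_deg must divide 360", call. = FALSE)
  }
  seg_ms <- spec$modulated_s * 1000
  n_cycles <- floor(spec$modulated_s * spec$f_mod)
  if (n_cycles < 1) stop("modulated segment contains no complete cycle",
                         call. = FALSE)
  inside <- spike_times >= 0 & spike_times < seg_ms
  theta <- stimulus_phase_deg(spike_times[inside], spec$f_mod)
  edges <- seq(0, 360, by = bin_deg)
  counts <- as.numeric(table(cut(theta, edges, right = FALSE,
                                 include.lowest = TRUE)))
  bin_s <- (bin_deg / 360) / spec$f_mod        # seconds spanned per cycle
  out <- tibble::tibble(
    bin_center_deg = edges[-length(edges)] + bin_deg / 2,
    count = counts,
    rate_hz = counts / (n_cycles * n_sweeps * bin_s)
  )
  class(out) <- c("glu_psth", class(out))
  attr(out, "f_mod") <- spec$f_mod
  attr(out, "n_cycles") <- n_cycles
  attr(out, "n_sweeps") <- n_sweeps
  attr(out, "bin_deg") <- bin_deg
  out
}

#' Fit a sine wave to a cycle-folded PSTH
#'
#' Least-squares fit of `offset + amplitude * sin(2*pi*n*theta/360 + phi0)`
#' with the number of cycles per stimulus period `n` free — the key
#' statistic separating two-peaked (onset + offset, n near 2) from
#' single-peaked (n near 1) responses.  For each candidate `n` the
#' amplitude/phase pair is a linear solve; `n` itself is found by a grid
#' scan refined with golden-section search.  A flat PSTH yields an
#' `amplitude ~ 0` fit flagged `degenerate`.
#'
#' @param psth A `glu_psth` from [build_psth()] (>= 8 bins).
#' @param n_range Search range for cycles per period.
#' @return An object of class `psth_sine_fit`: `amplitude` (spikes/s),
#'   `cycles_per_period`, `phase_deg` (phase offset in `[0, 360)`),
#'   `offset`, `goodness` (residual norm), `degenerate` flag.
#' @export
fit_sine <- function(psth, n_range = c(0.25, 4)) {
  if (nrow(psth) < 8) stop("need at least 8 PSTH bins", call. = FALSE)
  theta <- psth$bin_center_deg
  y <- psth$rate_hz
  solve_n <- function(n) {
    X <- cbind(1, sin(2 * pi * n * theta / 360), cos(2 * pi * n * theta / 360))
    fit <- stats::lm.fit(X, y)
    list(sse = sum(fit$residuals^2), coef = fit$coefficients)
  }
  grid <- seq(n_range[1], n_range[2], by = 0.01)
  sse <- vapply(grid, function(n) solve_n(n)$sse, numeric(1))
  n0 <- grid[which.min(sse)]
  opt <- stats::optimize(function(n) solve_n(n)$sse,
                         lower = max(n_range[1], n0 - 0.02),
                         upper = min(n_range[2], n0 + 0.02))
  n_best <- opt$minimum
  cf <- unname(solve_n(n_best)$coef)
  a <- cf[2]; b <- cf[3]
  amplitude <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) * 180 / pi) %% 360
  degenerate <- amplitude < 1e-6 * max(1, abs(cf[1])) ||
    stats::sd(y) < 1e-12
  structure(list(amplitude = amplitude,
                 cycles_per_period = n_best,
                 phase_deg = phase,
                 offset = cf[1],
                 goodness = sqrt(opt$objective),
                 degenerate = degenerate,
                 psth = psth),
            class = "psth_sine_fit")
}

#' @export
print.psth_sine_fit <- function(x, ...) {
  cat(sprintf(
    "<psth_sine_fit> %.2f cycles/period | amplitude %.2f Hz | offset %.2f Hz%s\n",
    x$cycles_per_period, x$amplitude, x$offset,
    if (x$degenerate) " | DEGENERATE (flat PSTH)" else ""))
  invisible(x)
}

#' Evaluate a fitted PSTH sine at given phases
#'
#' @param object A `psth_sine_fit`.
#' @param theta_deg Phases in degrees.
#' @param ... Unused.
#' @return Fitted rates in spikes/s.
#' @export
predict.psth_sine_fit <- function(object, theta_deg, ...) {
  object$offset + object$amplitude *
    sin(2 * pi * object$cycles_per_period * theta_deg / 360 +
        object$phase_deg * pi / 180)
}

#' Phase of the offset-response peak
#'
#' The offset response is firing as the stimulus rate falls; its peak is
#' taken as the maximum of the fitted sine curve within the offset
#' half-cycle (90°–360°), evaluated on a fine grid — robust to bin noise.
#' If the curve has no interior maximum there the result carries
#' `attr(, "flagged") = TRUE`.
#'
#' @param fit A `psth_sine_fit` (or a `glu_psth`, which is fit first).
#' @param grid_deg Evaluation resolution in degrees.
#' @return Peak phase in degrees.
#' @export
offset_peak_phase <- function(fit, grid_deg = 0.1) {
  if (inherits(fit, "glu_psth")) fit <- fit_sine(fit)
  stopifnot(inherits(fit, "psth_sine_fit"))
  theta <- seq(90, 360, by = grid_deg)
  yhat <- predict(fit, theta)
  peak <- theta[which.max(yhat)]
  flagged <- fit$degenerate || peak %in% range(theta)
  structure(peak, flagged = flagged)
}

#' Convert a phase shift to a time delay
#'
#' @param delta_deg Phase shift in degrees.
#' @param f_mod Modulation frequency in Hz (> 0).
#' @return Delay in ms: `delta_deg / 360 * 1000 / f_mod`.
#' @examples
#' phase_to_delay(77, 1)    # ~214 ms
#' phase_to_delay(90, 3)    # 83.3 ms
#' @export
phase_to_delay <- function(delta_deg, f_mod) {
  if (any(f_mod <= 0)) stop("f_mod must be positive (Hz)", call. = FALSE)
  delta_deg / 360 * 1000 / f_mod
}
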