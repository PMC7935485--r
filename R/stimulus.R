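#' Specification of the frequency-modulated stimulation protocol
#'
#' The in-vivo-like protocol: `silence_s` seconds without stimulation,
#' `conditioning_s` seconds of constant-rate stimulation at the carrier
#' frequency, then `modulated_s` seconds in which the instantaneous rate is
#' sinusoidally modulated around the carrier:
#' `rate(t) = carrier + depth * cos(2*pi*f_mod*t)` (t from the start of the
#' modulated segment).  The canonical protocol pairs are modulation
#' frequencies 0.3, 1 and 3 Hz with depths 6, 40 and 120 Hz respectively;
#' other combinations are accepted for exploration.
#'
#' @param carrier Carrier rate, Hz (default 26).
#' @param f_mod Modulation frequency, Hz (default 1).
#' @param depth Modulation depth: the rate excursion in Hz (default 40).
#' @param silence_s,conditioning_s,modulated_s Segment durations in s.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(carrier = 26, f_mod = 1, depth = 40,
                          silence_s = 5, conditioning_s = 10,
                          modulated_s = 10) {
  if (carrier <= 0 || f_mod <= 0) stop("carrier and f_mod must be positive",
                                       call. = FALSE)
  if (depth < 0) stop("depth must be nonnegative", call. = FALSE)
  if (silence_s < 0 || conditioning_s < 0 || modulated_s < 0) {
    stop("segment durations must be nonnegative", call. = FALSE)
  }
  structure(list(carrier = carrier, f_mod = f_mod, depth = depth,
                 silence_s = silence_s, conditioning_s = conditioning_s,
                 modulated_s = modulated_s),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> carrier %g Hz | f_mod %g Hz | depth %g Hz | %g+%g+%g s\n",
    x$carrier, x$f_mod, x$depth, x$silence_s, x$conditioning_s,
    x$modulated_s))
  invisible(x)
}

new_stim_train <- function(event_times, spec = NULL) {
  if (length(event_times) > 1 && any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (length(event_times) && any(event_times < 0)) {
    stop("event times must be nonnegative", call. = FALSE)
  }
  structure(list(event_times = as.numeric(event_times), spec = spec,
                 convention = "rate = carrier + depth*cos(2*pi*f_mod*t)"),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  n <- length(x$event_times)
  cat(sprintf("<stim_train> %d events%s\n", n,
              if (n) sprintf(" spanning %.1f-%.1f ms", x$event_times[1],
                             x$event_times[n]) else ""))
  invisible(x)
}

#' @export
as_tibble.stim_train <- function(x, ...) {
  tibble::tibble(event = seq_along(x$event_times), time_ms = x$event_times)
}

#' Constant-frequency stimulus train
#'
#' Events evenly spaced at `1000/rate` ms, the first at `start_ms`.
#'
#' @param rate Stimulation rate, Hz (> 0).
#' @param n Number of events; alternatively give `duration_s`.
#' @param duration_s Train duration in s (`floor(duration_s * rate)` events).
#' @param start_ms Time of the first event, ms.
#' @return A `stim_train`.
#' @examples
#' length(constant_train(26, duration_s = 10)$event_times)  # 260
#' @export
constant_train <- function(rate, n = NULL, duration_s = NULL, start_ms = 0) {
  if (rate <= 0) stop("rate must be positive (Hz)", call. = FALSE)
  if (is.null(n)) {
    if (is.null(duration_s)) stop("give n or duration_s", call. = FALSE)
    n <- floor(duration_s * rate)
  }
  new_stim_train(start_ms + (seq_len(n) - 1) * 1000 / rate,
                 spec = stimulus_spec(carrier = rate))
}

#' Frequency-modulated stimulus train
#'
#' Event times are the first forward crossings of integer stimulus cycles of
#' the phase \eqn{\phi(t) = 2\pi\,carrier\,t + (d/f)\sin(2\pi f t)}, whose
#' derivative is the instantaneous rate `carrier + d*cos(2*pi*f*t)` — so
#' "depth" is exactly the rate excursion in Hz (extrema `carrier ± d`).
#' When `d > carrier` the instantaneous rate goes negative and the phase
#' retreats; such intervals emit no events and a cycle already crossed is
#' never emitted twice.  The result is deterministic.
#'
#' @param spec A [stimulus_spec()]; `modulated_s` sets the duration unless
#'   `duration_s` is given.
#' @param duration_s Optional duration override, s.
#' @param start_ms Time origin of the modulated segment, ms.
#' @param dt_ms Internal phase-sampling resolution, ms.
#' @return A `stim_train` (first event at `start_ms`, phase 0).
#' @export
fm_train <- function(spec, duration_s = spec$modulated_s, start_ms = 0,
                     dt_ms = 0.02) {
  stopifnot(inherits(spec, "stimulus_spec"))
  t <- seq(0, duration_s * 1000, by = dt_ms)   # ms
  ts <- t / 1000                               # s
  phi <- 2 * pi * spec$carrier * ts
  if (spec$depth > 0) {
    phi <- phi + (spec$depth / spec$f_mod) * sin(2 * pi * spec$f_mod * ts)
  }
  m <- cummax(phi)
  n_cycles <- floor(m[length(m)] / (2 * pi) * (1 + 1e-12))
  targets <- 2 * pi * seq_len(n_cycles)
  # first index where the running max reaches each target
  idx <- findInterval(targets * (1 - 1e-12), m) + 1L
  idx <- pmin(idx, length(m))
  t_prev <- t[idx - 1L]
  num <- targets - phi[idx - 1L]
  den <- phi[idx] - phi[idx - 1L]
  frac <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 1)
  times <- c(0, t_prev + frac * dt_ms)
  new_stim_train(start_ms + times, spec = spec)
}

#' Full stimulation protocol: silence, conditioning, modulation
#'
#' Concatenates the three protocol segments on a continuous time base:
#' no events during `silence_s`, a constant carrier-rate train during
#' `conditioning_s`, then the frequency-modulated train for `modulated_s`.
#'
#' @param spec A [stimulus_spec()].
#' @return A `stim_train` with attribute-free continuous event times; the
#'   modulated segment starts at `(silence_s + conditioning_s) * 1000` ms.
#' @export
full_protocol <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  cond <- constant_train(spec$carrier, duration_s = spec$conditioning_s,
                         start_ms = spec$silence_s * 1000)
  mod <- fm_train(spec, start_ms = (spec$silence_s + spec$conditioning_s) * 1000)
  new_stim_train(c(cond$event_times, mod$event_times), spec = spec)
}

#' Start time of the modulated segment of a protocol, ms
#'
#' @param spec A [stimulus_spec()].
#' @return Time in ms.
#' @export
modulation_start_ms <- function(spec) {
  (spec$silence_s + spec$conditioning_s) * 1000
}

#' Write / read a stimulus train as plain text
#'
#' One event time (ms) per line, serialized to µs precision, preceded by a
#' `#` comment header carrying the protocol metadata and the adopted
#' rate-modulation convention.  The format is importable into acquisition
#' software that accepts event-time lists.  `read_train()` errors on
#' unsorted files.
#'
#' @param train A `stim_train`.
#' @param path File path.
#' @return `write_train()`: `path` invisibly; `read_train()`: a `stim_train`.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "stim_train"))
  hdr <- c("# ambientglu stimulus train", "# units: ms")
  if (!is.null(train$spec)) {
    s <- train$spec
    hdr <- c(hdr,
             sprintf("# carrier_hz: %g", s$carrier),
             sprintf("# f_mod_hz: %g", s$f_mod),
             sprintf("# depth_hz: %g", s$depth),
             sprintf("# convention: %s", train$convention))
  }
  writeLines(c(hdr, sprintf("%.3f", train$event_times)), path)
  invisible(path)
}

#' @rdname write_train
#' @export
read_train <- function(path) {
  if (!file.exists(path)) stop("train file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  times <- suppressWarnings(as.numeric(body))
  if (any(is.na(times))) {
    stop(sprintf("train file %s: non-numeric event time on line %d", path,
                 which(is.na(times))[1]), call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("train file events are not strictly increasing", call. = FALSE)
  }
  new_stim_train(times)
}
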