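AVOGADRO <- 6.02214076e23
# molecules / um^3  ->  uM   (1 um^3 = 1e-15 L; mol/um^3 = 1e21 uM)
MOLEC_UM3_TO_UM <- 1e21 / AVOGADRO

#' Parameters of the point-source glutamate transient
#'
#' Describes a single instantaneous release of `M` glutamate molecules into
#' brain extracellular space, sensed at a 3D distance `r` from the release
#' point.  Diffusion is hindered by tortuosity (`D_eff = D / lam^2`) and the
#' released molecules are concentrated into the extracellular volume fraction
#' `alpha`.  A flat `ambient` concentration floor is added on top — the
#' standing extracellular glutamate between release events, the central
#' quantity this package infers.
#'
#' @param M Molecules released per event (converted to moles internally).
#' @param r Distance from release site to the receptors, µm (> 0).
#' @param alpha Extracellular volume fraction (default 0.21).
#' @param D Free diffusion coefficient in µm²/ms (default 0.33).
#' @param lam Tortuosity λ (default 1.55).
#' @param ambient Ambient glutamate concentration in µM (>= 0).
#' @return An object of class `transient_params`.
#' @export
transient_params <- function(M, r, alpha = 0.21, D = 0.33, lam = 1.55,
                             ambient = 0) {
  if (!is.finite(r) || r <= 0) stop("r must be a positive distance (um)",
                                    call. = FALSE)
  if (!is.finite(M) || M < 0) stop("M must be a nonnegative molecule count",
                                   call. = FALSE)
  if (alpha <= 0 || D <= 0 || lam <= 0) {
    stop("alpha, D and lam must be positive", call. = FALSE)
  }
  if (!is.finite(ambient) || ambient < 0) {
    stop("ambient must be a nonnegative concentration (uM)", call. = FALSE)
  }
  structure(list(M = M, r = r, alpha = alpha, D = D, lam = lam,
                 ambient = ambient),
            class = "transient_params")
}

#' @export
print.transient_params <- function(x, ...) {
  cat(sprintf(
    "<transient_params> M = %.3g molecules | r = %g um | ambient = %g uM\n",
    x$M, x$r, x$ambient))
  cat(sprintf("  alpha = %g, D = %g um^2/ms, lambda = %g (D_eff = %.5g um^2/ms)\n",
              x$alpha, x$D, x$lam, effective_diffusion(x$D, x$lam)))
  invisible(x)
}

#' Effective diffusion coefficient in tortuous extracellular space
#'
#' @param D Free diffusion coefficient (µm²/ms).
#' @param lam Tortuosity λ (> 0).
#' @return `D / lam^2` in µm²/ms.
#' @export
effective_diffusion <- function(D, lam) {
  if (any(lam <= 0)) stop("lam must be positive", call. = FALSE)
  D / lam^2
}

#' Glutamate concentration transient from one release event
#'
#' The instantaneous point-source solution of the 3D diffusion equation in
#' tortuous extracellular space, divided by the volume fraction, plus the
#' ambient floor:
#' \deqn{C(\tau) = \frac{M}{8\,\alpha\,(\pi D_{eff} \tau)^{3/2}}
#'       \exp\!\left(-\frac{r^2}{4 D_{eff} \tau}\right) + ambient,}
#' with \eqn{D_{eff} = D/\lambda^2} and \eqn{\tau = t - t_0}.  For
#' \eqn{\tau \le 0} the ambient value is returned.  The peak at distance `r`
#' occurs at \eqn{\tau = r^2 / (6 D_{eff})}.
#'
#' @param params A [transient_params()].
#' @param t Time(s) in ms (vectorized).
#' @param t0 Event time in ms.
#' @return Concentration(s) in µM.
#' @export
glu_transient <- function(params, t, t0 = 0) {
  stopifnot(inherits(params, "transient_params"))
  tau <- t - t0
  deff <- effective_diffusion(params$D, params$lam)
  out <- rep(params$ambient, length(tau))
  pos <- tau > 0
  if (any(pos)) {
    tp <- tau[pos]
    amp <- params$M * MOLEC_UM3_TO_UM /
      (8 * params$alpha * (pi * deff * tp)^1.5)
    out[pos] <- amp * exp(-params$r^2 / (4 * deff * tp)) + params$ambient
  }
  out
}

#' Time of the transient peak at distance r
#'
#' Closed form `r^2 / (6 D_eff)` from differentiating the point-source
#' kernel.
#'
#' @param params A [transient_params()].
#' @return Peak time in ms after the release event.
#' @export
transient_peak_time <- function(params) {
  params$r^2 / (6 * effective_diffusion(params$D, params$lam))
}

#' Glutamate concentration time course for a stimulus train
#'
#' Single-event transients are superposed linearly (no presynaptic
#' depression), each event releasing the same `M` at the same distance `r`;
#' the ambient floor is added exactly once.
#'
#' @param params A [transient_params()].
#' @param events Event times in ms: a numeric vector or a `stim_train`.
#' @param tgrid Output time grid in ms (sorted).
#' @return A tibble `time_ms`, `glu_uM`.
#' @export
train_concentration <- function(params, events, tgrid) {
  if (inherits(events, "stim_train")) events <- events$event_times
  events <- as.numeric(events)
  if (length(events) > 1 && any(diff(events) < 0)) {
    stop("event times must be sorted increasing", call. = FALSE)
  }
  conc <- rep(params$ambient, length(tgrid))
  for (t0 in events) {
    conc <- conc + (glu_transient(params, tgrid, t0) - params$ambient)
  }
  tibble::tibble(time_ms = tgrid, glu_uM = conc)
}
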