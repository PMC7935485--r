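#' Preprocess a recorded current trace
#'
#' Mirrors the experimental conditioning chain applied to whole-cell
#' recordings before fitting: trial averaging, blanking of stimulation
#' artifacts (each window replaced by linear interpolation between its
#' endpoints), and zero-phase low-pass filtering (4th-order Butterworth run
#' forward and backward).  Blanking precedes filtering so artifact energy
#' cannot ring through the filter.
#'
#' @param trace A trace tibble (`time_ms`, `current_pA`) or a list of such
#'   tibbles sharing one time grid, which are averaged.
#' @param artifact_windows Optional 2-column matrix (or list of length-2
#'   vectors) of `(start_ms, end_ms)` windows to blank.
#' @param filter_cutoff Low-pass cutoff in Hz (default 1000); `NULL` or
#'   `Inf` disables filtering.
#' @return A preprocessed trace tibble.
#' @export
preprocess_trace <- function(trace, artifact_windows = NULL,
                             filter_cutoff = 1000) {
  if (is.data.frame(trace)) trace <- list(trace)
  t0 <- trace[[1]]$time_ms
  for (tr in trace) {
    if (!identical(nrow(tr), length(t0)) || max(abs(tr$time_ms - t0)) > 1e-9) {
      stop("traces to average must share one time grid", call. = FALSE)
    }
  }
  y <- rowMeans(do.call(cbind, lapply(trace, `[[`, "current_pA")))
  if (!is.null(artifact_windows)) {
    if (is.list(artifact_windows)) {
      artifact_windows <- do.call(rbind, artifact_windows)
    }
    w <- artifact_windows[order(artifact_windows[, 1]), , drop = FALSE]
    if (any(w[, 2] <= w[, 1])) {
      stop("artifact window with end <= start", call. = FALSE)
    }
    if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2])) {
      stop("artifact windows overlap", call. = FALSE)
    }
    if (min(w) < min(t0) || max(w) > max(t0)) {
      stop("artifact window outside the trace span", call. = FALSE)
    }
    for (k in seq_len(nrow(w))) {
      inside <- t0 > w[k, 1] & t0 < w[k, 2]
      if (!any(inside)) next
      keep <- !inside
      y[inside] <- stats::approx(t0[keep], y[keep], xout = t0[inside],
                                 rule = 2)$y
    }
  }
  dt <- stats::median(diff(t0))
  if (!is.null(filter_cutoff) && is.finite(filter_cutoff)) {
    y <- lowpass_filtfilt(y, fs_hz = 1000 / dt, cutoff_hz = filter_cutoff)
  }
  tibble::tibble(time_ms = t0, current_pA = y)
}

# zero-phase 4th-order Butterworth low-pass; no-op if cutoff >= Nyquist.
# Odd-reflection padding suppresses the end transients filtfilt would
# otherwise produce on traces with a DC offset.
lowpass_filtfilt <- function(y, fs_hz, cutoff_hz) {
  wc <- cutoff_hz / (fs_hz / 2)
  if (wc >= 1) return(y)
  filt <- signal::butter(4, wc)
  n <- length(y)
  y0 <- mean(y)
  y <- y - y0
  npad <- min(n - 1, ceiling(12 * fs_hz / cutoff_hz))
  ypad <- c(2 * y[1] - y[(npad + 1):2], y, 2 * y[n] - y[(n - 1):(n - npad)])
  out <- signal::filtfilt(filt, ypad)
  out[(npad + 1):(npad + n)] + y0
}

# ratio of post-filtfilt white-noise sd to input sd (deterministic, from the
# squared magnitude response of the forward-backward filter)
filtfilt_noise_sd_factor <- function(fs_hz, cutoff_hz, n = 2048) {
  wc <- cutoff_hz / (fs_hz / 2)
  if (wc >= 1) return(1)
  filt <- signal::butter(4, wc)
  h <- signal::freqz(filt, n = n)$h
  sqrt(mean(Mod(h)^4))
}

#' Simulate the synaptic AMPAR current for a stimulus train
#'
#' The forward model of the package: the glutamate concentration time course
#' at the receptors (linear superposition of point-source transients over
#' the train, on the ambient floor) drives the 13-state receptor scheme,
#' starting from equilibrium at the ambient concentration (tonic
#' desensitization is part of the initial condition); the open-state
#' occupancy is converted to current and a constant leak offset added.
#'
#' @param scheme A [rate_scheme()].
#' @param params A [transient_params()] (includes `ambient`).
#' @param train Event times in ms (numeric or `stim_train`).
#' @param tgrid Uniform output time grid in ms.
#' @param v,Erev Voltage parameters, mV.
#' @param leak_offset Constant leak current, pA.
#' @param glu_rtol Concentration tolerance for matrix-exponential reuse
#'   during propagation (0 = exact; small values speed up fitting).
#' @return A trace tibble `time_ms`, `current_pA`.
#' @export
simulate_current <- function(scheme, params, train, tgrid, v = -70,
                             Erev = 0, leak_offset = 0, glu_rtol = 0) {
  glu <- train_concentration(params, train, tgrid)
  init <- equilibrium_occupancy(scheme, params$ambient)
  occ <- propagate(scheme, glu, initial = init, glu_rtol = glu_rtol)
  out <- receptor_current(occ, scheme, v = v, Erev = Erev)
  out$current_pA <- out$current_pA + leak_offset
  out
}

.fit_par_names <- c("M", "r", "ambient", "g_max", "leak_offset")
.fit_log_pars <- c("M", "r", "ambient", "g_max")

#' Specification of a current-trace fit
#'
#' Declares which forward-model parameters are free, their bounds and
#' initial values, and the optimizer budget.  Positive parameters are
#' optimized on a log scale; `leak_offset` on a linear scale.  The optimizer
#' is a bounded derivative-free simplex (Nelder–Mead with out-of-bounds
#' penalty) restarted from jittered initial points; restart spread is the
#' only uncertainty surrogate reported.
#'
#' @param free Character subset of `c("M","r","ambient","g_max","leak_offset")`.
#' @param init Named initial values (natural scale), inside the bounds.
#' @param lower,upper Named finite bounds (natural scale).
#' @param max_evals Maximum objective evaluations per optimizer start.
#' @param restarts Number of jittered restarts in addition to the plain start.
#' @param jitter_sd Restart jitter s.d. on the transformed scale.
#' @param seed Integer seed making the whole fit deterministic.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("M", "r", "ambient", "g_max", "leak_offset"),
                     init = c(M = 5e6, r = 1.23, ambient = 4.7, g_max = 5,
                              leak_offset = -10),
                     lower = c(M = 1e4, r = 0.2, ambient = 0.01,
                               g_max = 0.2, leak_offset = -300),
                     upper = c(M = 1e9, r = 6, ambient = 100, g_max = 100,
                               leak_offset = 300),
                     max_evals = 400, restarts = 2, jitter_sd = 0.15,
                     seed = 1) {
  free <- match.arg(free, .fit_par_names, several.ok = TRUE)
  for (nm in .fit_par_names) {
    if (is.na(init[nm]) || is.na(lower[nm]) || is.na(upper[nm])) {
      stop("init, lower and upper must all name parameter ", nm,
           call. = FALSE)
    }
  }
  init <- init[.fit_par_names]; lower <- lower[.fit_par_names]
  upper <- upper[.fit_par_names]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  if (any(init < lower | init > upper)) {
    bad <- .fit_par_names[init < lower | init > upper][1]
    stop("initial value for ", bad, " lies outside its bounds",
         call. = FALSE)
  }
  structure(list(free = free, init = init, lower = lower, upper = upper,
                 max_evals = max_evals, restarts = restarts,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "fit_spec")
}

# natural <-> transformed coordinates for the free parameters
.to_z <- function(p, free) {
  z <- numeric(length(free))
  for (i in seq_along(free)) {
    z[i] <- if (free[i] %in% .fit_log_pars) log(p[[free[i]]])
            else p[[free[i]]] / 50
  }
  z
}
.from_z <- function(z, free) {
  p <- numeric(length(free))
  for (i in seq_along(free)) {
    p[i] <- if (free[i] %in% .fit_log_pars) exp(z[i]) else z[i] * 50
  }
  stats::setNames(p, free)
}

# TRUE where a sample is outside every excluded (blanked-artifact) window
.window_mask <- function(time_ms, windows) {
  mask <- rep(TRUE, length(time_ms))
  if (is.null(windows)) return(mask)
  if (is.list(windows)) windows <- do.call(rbind, windows)
  for (k in seq_len(nrow(windows))) {
    mask[time_ms >= windows[k, 1] & time_ms <= windows[k, 2]] <- FALSE
  }
  mask
}

# Build the least-squares objective: mean squared residual (pA^2) between the
# preprocessed data and the identically filtered simulated current, over the
# fit window (the full trace minus the blanked artifact windows).
.make_objective <- function(data, train, scheme, spec, fixed, v, Erev,
                            alpha, D, lam, filter_cutoff, glu_rtol,
                            exclude_windows = NULL) {
  tgrid <- data$time_ms
  dt <- stats::median(diff(tgrid))
  fs <- 1000 / dt
  y <- data$current_pA
  mask <- .window_mask(tgrid, exclude_windows)
  zl <- .to_z(as.list(spec$lower), spec$free)
  zu <- .to_z(as.list(spec$upper), spec$free)
  sim_for <- function(par) {
    tp <- transient_params(M = par[["M"]], r = par[["r"]], alpha = alpha,
                           D = D, lam = lam, ambient = par[["ambient"]])
    sch <- scheme
    sch$g_max <- par[["g_max"]]
    sim <- simulate_current(sch, tp, train, tgrid, v = v, Erev = Erev,
                            leak_offset = par[["leak_offset"]],
                            glu_rtol = glu_rtol)
    if (!is.null(filter_cutoff) && is.finite(filter_cutoff)) {
      sim$current_pA <- lowpass_filtfilt(sim$current_pA, fs, filter_cutoff)
    }
    sim
  }
  full_par <- function(z) {
    zc <- pmin(pmax(z, zl), zu)
    p <- fixed
    p[spec$free] <- .from_z(zc, spec$free)
    p
  }
  obj <- function(z) {
    zc <- pmin(pmax(z, zl), zu)
    over <- sum((z - zc)^2)
    p <- full_par(z)
    sim <- sim_for(p)
    mse <- mean((sim$current_pA[mask] - y[mask])^2)
    mse * (1 + 10 * over) + over
  }
  list(obj = obj, sim_for = sim_for, full_par = full_par, zl = zl, zu = zu,
       mask = mask)
}

.run_fit <- function(data, train, scheme, spec, fixed, v, Erev, alpha, D,
                     lam, filter_cutoff, glu_rtol, condition,
                     control_fit = NULL, exclude_windows = NULL) {
  machinery <- .make_objective(data, train, scheme, spec, fixed, v, Erev,
                               alpha, D, lam, filter_cutoff, glu_rtol,
                               exclude_windows)
  z0 <- .to_z(as.list(spec$init), spec$free)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  starts <- c(list(z0), lapply(seq_len(spec$restarts), function(i) {
    pmin(pmax(z0 + stats::rnorm(length(z0), 0, spec$jitter_sd),
              machinery$zl), machinery$zu)
  }))
  runs <- lapply(starts, function(zs) {
    if (length(zs) == 1) {
      stats::optim(zs, machinery$obj, method = "Brent",
                   lower = machinery$zl, upper = machinery$zu,
                   control = list(maxit = spec$max_evals))
    } else {
      stats::optim(zs, machinery$obj, method = "Nelder-Mead",
                   control = list(maxit = spec$max_evals,
                                  reltol = 1e-9))
    }
  })
  objs <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(objs)]]
  par <- machinery$full_par(best$par)
  restart_pars <- do.call(rbind, lapply(runs, function(r) {
    machinery$full_par(r$par)[spec$free]
  }))
  fitted <- machinery$sim_for(par)
  residuals <- tibble::tibble(time_ms = data$time_ms,
                              residual_pA = data$current_pA -
                                fitted$current_pA)
  structure(list(
    par = par,
    free = spec$free,
    objective = mean(residuals$residual_pA[machinery$mask]^2),
    exclude_windows = exclude_windows,
    restart_objectives = objs,
    restart_spread = apply(restart_pars, 2, stats::sd),
    converged = any(vapply(runs, `[[`, numeric(1), "convergence") == 0),
    fitted = fitted,
    residuals = residuals,
    data = data,
    train = if (inherits(train, "stim_train")) train$event_times
            else as.numeric(train),
    spec = spec,
    volts = c(v = v, Erev = Erev),
    condition = condition,
    control_fit = control_fit,
    seed = spec$seed
  ), class = "glu_fit")
}

#' Fit the forward model to a recorded control trace
#'
#' Least-squares fit (mean squared residual over the trace) of the simulated
#' synaptic current to a preprocessed recorded trace, varying the free
#' parameters of `spec` — typically the amount of glutamate released `M`,
#' the release–receptor distance `r`, the `ambient` concentration, the
#' maximal conductance `g_max` and a constant `leak_offset`.  Derivative-free
#' simplex search on log-transformed positive parameters with jittered
#' restarts; deterministic given `spec$seed`.  Non-convergence is flagged on
#' the result (`converged = FALSE`), not raised.
#'
#' @param data Preprocessed trace tibble (`time_ms`, `current_pA`).
#' @param train Stimulus event times, ms.
#' @param scheme A [rate_scheme()] (already Q10-scaled to the recording
#'   temperature).
#' @param spec A [fit_spec()].
#' @param v,Erev Voltage parameters, mV.
#' @param alpha,D,lam Fixed extracellular diffusion parameters.
#' @param filter_cutoff Low-pass cutoff (Hz) applied to the simulated trace
#'   so model and data see the same filtering; match the preprocessing.
#' @param glu_rtol Matrix-exponential reuse tolerance during fitting.
#' @param exclude_windows Optional `(start_ms, end_ms)` windows (matrix or
#'   list) excluded from the objective — pass the blanked artifact windows
#'   so interpolated samples do not weigh on the fit.
#' @return A `glu_fit` object; see [tidy.glu_fit()], [glance.glu_fit()],
#'   [autoplot.glu_fit()].
#' @export
fit_control <- function(data, train, scheme, spec = fit_spec(),
                        v = -70, Erev = 0, alpha = 0.21, D = 0.33,
                        lam = 1.55, filter_cutoff = 1000,
                        glu_rtol = 2e-2, exclude_windows = NULL) {
  fixed <- spec$init
  .run_fit(data, train, scheme, spec, fixed, v, Erev, alpha, D, lam,
           filter_cutoff, glu_rtol, condition = "control",
           exclude_windows = exclude_windows)
}

#' Refit a transporter-block trace from a paired control fit
#'
#' Reproduces the two-stage protocol: after the full control fit, the
#' EAAT-block (e.g. DL-TBOA) trace from the same cell is refit varying only
#' the ambient concentration and the amount of glutamate released — all
#' other parameters are inherited frozen from the control fit.  Optionally
#' the maximal conductance is also freed (`allow_gmax`), the fallback needed
#' when block reveals spillover onto receptors unreachable in control.
#'
#' @param data Preprocessed block-condition trace tibble.
#' @param train Stimulus event times, ms.
#' @param scheme A [rate_scheme()].
#' @param control_fit The paired control `glu_fit`.
#' @param allow_gmax Free `g_max` as well? (default `FALSE`).
#' @param spec Optional [fit_spec()] overriding bounds/budget; its `free`
#'   set is replaced by the block free set and its `init` by the control
#'   estimates.
#' @param v,Erev,alpha,D,lam,filter_cutoff,glu_rtol,exclude_windows As in
#'   [fit_control()].
#' @return A `glu_fit` with `condition = "eaat_block"` and the control fit
#'   attached.
#' @export
fit_eaat_block <- function(data, train, scheme, control_fit,
                           allow_gmax = FALSE, spec = NULL, v = -70,
                           Erev = 0, alpha = 0.21, D = 0.33, lam = 1.55,
                           filter_cutoff = 1000, glu_rtol = 2e-2,
                           exclude_windows = NULL) {
  if (!inherits(control_fit, "glu_fit")) {
    stop("fit_eaat_block requires the paired control glu_fit", call. = FALSE)
  }
  if (is.null(spec)) spec <- control_fit$spec
  free <- c("ambient", "M", if (allow_gmax) "g_max")
  init <- control_fit$par[.fit_par_names]
  spec2 <- fit_spec(free = free, init = init, lower = spec$lower,
                    upper = spec$upper, max_evals = spec$max_evals,
                    restarts = spec$restarts, jitter_sd = spec$jitter_sd,
                    seed = spec$seed)
  fixed <- control_fit$par
  .run_fit(data, train, scheme, spec2, fixed, v, Erev, alpha, D, lam,
           filter_cutoff, glu_rtol, condition = "eaat_block",
           control_fit = control_fit, exclude_windows = exclude_windows)
}

#' Evaluate the fit objective at given parameter values
#'
#' Mean squared residual (pA²) between a preprocessed trace and the
#' identically filtered forward simulation at a fixed parameter vector —
#' useful for comparing a fitted model across conditions or samplings
#' without re-optimizing.
#'
#' @param par Named vector with `M`, `r`, `ambient`, `g_max`, `leak_offset`
#'   (e.g. the `par` element of a `glu_fit`).
#' @param data Preprocessed trace tibble.
#' @param train Stimulus event times, ms.
#' @param scheme A [rate_scheme()].
#' @inheritParams fit_control
#' @return The mean squared residual in pA² over the fit window.
#' @export
fit_objective <- function(par, data, train, scheme, v = -70, Erev = 0,
                          alpha = 0.21, D = 0.33, lam = 1.55,
                          filter_cutoff = 1000, glu_rtol = 0,
                          exclude_windows = NULL) {
  spec <- fit_spec(free = "M",
                   init = par[.fit_par_names],
                   lower = pmin(par[.fit_par_names] - 1,
                                c(M = 1e3, r = 0.01, ambient = 1e-4,
                                  g_max = 0.01, leak_offset = -1e4)),
                   upper = pmax(par[.fit_par_names] + 1,
                                c(M = 1e10, r = 100, ambient = 1e4,
                                  g_max = 1e3, leak_offset = 1e4)))
  machinery <- .make_objective(data, train, scheme, spec,
                               fixed = par[.fit_par_names], v, Erev, alpha,
                               D, lam, filter_cutoff, glu_rtol,
                               exclude_windows)
  sim <- machinery$sim_for(par[.fit_par_names])
  mean((sim$current_pA[machinery$mask] -
          data$current_pA[machinery$mask])^2)
}

#' Percent error reduction between two nested fits
#'
#' `100 * (1 - obj_with / obj_without)`: how much the fit error (square
#' norm) shrinks when a parameter — canonically the ambient concentration —
#' is added to the model.
#'
#' @param with_fit,without_fit `glu_fit` objects (or bare objective values)
#'   fit to the same data with nested free-parameter sets.
#' @return Percent reduction (positive when `with_fit` fits better).
#' @export
error_reduction <- function(with_fit, without_fit) {
  obj_w <- if (inherits(with_fit, "glu_fit")) with_fit$objective
           else as.numeric(with_fit)
  obj_wo <- if (inherits(without_fit, "glu_fit")) without_fit$objective
            else as.numeric(without_fit)
  if (obj_wo == 0) stop("reference fit has zero error", call. = FALSE)
  100 * (1 - obj_w / obj_wo)
}

#' @export
print.glu_fit <- function(x, ...) {
  cat(sprintf("<glu_fit> condition: %s | objective (mean sq. residual): %.4g pA^2\n",
              x$condition, x$objective))
  est <- x$par[x$free]
  cat("  free: ", paste(sprintf("%s = %.4g", names(est), est),
                        collapse = ", "), "\n", sep = "")
  if (!x$converged) {
    cat("  note: optimizer stopped at its evaluation budget before formal convergence\n")
  }
  invisible(x)
}
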