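#' Equilibrium occupancy of the scheme at a fixed glutamate concentration
#'
#' Solves the null space of the generator matrix (the stationary distribution
#' of the continuous-time Markov chain) and normalizes it to sum to one.
#' Errors if the null space is not one-dimensional, which would indicate a
#' disconnected scheme.
#'
#' @param scheme A [rate_scheme()].
#' @param glu Glutamate concentration in µM (scalar >= 0).
#' @return Named numeric vector of 13 state probabilities.
#' @examples
#' sch <- default_rate_scheme()
#' eq <- equilibrium_occupancy(sch, 5)
#' eq[["C0"]]   # fraction of receptors free of agonist at 5 uM
#' @export
equilibrium_occupancy <- function(scheme, glu) {
  Q <- generator_matrix(scheme, glu)
  sv <- svd(Q)
  d <- sv$d
  n <- length(d)
  tol <- max(d) * 1e-10
  if (n > 1 && d[n - 1] < tol) {
    stop("generator has a degenerate null space; scheme appears disconnected",
         call. = FALSE)
  }
  p <- sv$v[, n]
  p <- p / sum(p)
  if (any(p < -1e-10)) {
    stop("equilibrium solve produced negative occupancy", call. = FALSE)
  }
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), ampar_states)
}

#' Propagate receptor occupancy under a time-varying glutamate concentration
#'
#' Integrates the master equation `dp/dt = Q(glu(t)) p` along a uniformly
#' sampled concentration trace, treating the concentration as piecewise
#' constant over each sampling interval.  Two integration paths are exposed:
#'
#' * `"expm"` (reference): one 13x13 matrix exponential per sample — exact
#'   for the piecewise-constant concentration, unconditionally stable.
#'   `glu_rtol` allows consecutive samples whose concentration differs by
#'   less than that relative tolerance to reuse the previous exponential
#'   (default 0: always exact).
#' * `"ode"` (cross-check): adaptive stiff integration with
#'   [deSolve::lsoda()] on the same piecewise-constant concentration.
#'
#' @param scheme A [rate_scheme()].
#' @param glu Concentration trace: a data frame with columns `time_ms` and
#'   `glu_uM` (uniformly sampled), or a numeric vector with `dt_ms` supplied.
#' @param initial Initial occupancy: a named 13-vector of probabilities, or
#'   `"equilibrium"` (default) to pre-equilibrate at the first concentration
#'   sample — tonic desensitization by ambient glutamate before stimulation
#'   is the phenomenon of interest, so protocols start from the ambient
#'   steady state.
#' @param method `"expm"` or `"ode"`.
#' @param dt_ms Sampling interval in ms when `glu` is a bare numeric vector.
#' @param glu_rtol Relative concentration tolerance for matrix-exponential
#'   reuse (`"expm"` only).
#' @param rtol,atol Tolerances for the `"ode"` path.
#' @param check_tol Maximum tolerated deviation of per-sample probability
#'   sums from 1 (and of occupancies below 0); violation is an error.
#' @return A tibble with `time_ms` and one column per state.
#' @export
propagate <- function(scheme, glu, initial = "equilibrium",
                      method = c("expm", "ode"), dt_ms = NULL,
                      glu_rtol = 0, rtol = 1e-8, atol = 1e-10,
                      check_tol = 1e-6) {
  method <- match.arg(method)
  if (is.data.frame(glu)) {
    time_ms <- glu$time_ms
    conc <- glu$glu_uM
    dt_ms <- stats::median(diff(time_ms))
  } else {
    conc <- as.numeric(glu)
    if (is.null(dt_ms)) stop("dt_ms required when glu is a bare vector",
                             call. = FALSE)
    time_ms <- (seq_along(conc) - 1) * dt_ms
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("glutamate concentrations must be finite and nonnegative",
         call. = FALSE)
  }
  if (identical(initial, "equilibrium")) {
    p0 <- equilibrium_occupancy(scheme, conc[1])
  } else {
    p0 <- initial[ampar_states]
    if (any(is.na(p0)) || abs(sum(p0) - 1) > 1e-8 || any(p0 < 0)) {
      stop("initial occupancy must be probabilities over the 13 states summing to 1",
           call. = FALSE)
    }
  }
  parts <- generator_parts(scheme)
  if (method == "expm") {
    occ <- .propagate_expm_cpp(parts$Q0, parts$Q1, conc, dt_ms,
                               as.numeric(p0), glu_rtol)
  } else {
    conc_fun <- stats::approxfun(time_ms, conc, method = "constant",
                                 rule = 2, f = 0)
    deriv <- function(t, p, parms) {
      list(as.numeric(parts$Q0 %*% p + conc_fun(t) * (parts$Q1 %*% p)))
    }
    sol <- deSolve::lsoda(as.numeric(p0), time_ms, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    occ <- unname(sol[, -1, drop = FALSE])
  }
  sums <- rowSums(occ)
  if (max(abs(sums - 1)) > check_tol || min(occ) < -check_tol) {
    stop(sprintf(
      "integration violated probability conservation (max |sum-1| = %.2e, min occupancy = %.2e)",
      max(abs(sums - 1)), min(occ)), call. = FALSE)
  }
  occ <- pmax(occ, 0) / sums
  colnames(occ) <- ampar_states
  dplyr::bind_cols(tibble::tibble(time_ms = time_ms),
                   tibble::as_tibble(occ))
}

#' AMPAR current from receptor occupancy
#'
#' Conductance is `g = g_max * sum_k w_k * P(O_k)` with the scheme's
#' open-state weights `w`; current is `g * (v - Erev)` (nS x mV = pA).
#'
#' @param occupancy Occupancy tibble from [propagate()] (column per state),
#'   or a named 13-vector.
#' @param scheme A [rate_scheme()].
#' @param v Holding potential in mV (default -70).
#' @param Erev Reversal potential in mV (default 0).
#' @return If `occupancy` is a tibble: a tibble `time_ms`, `current_pA`;
#'   if a vector: a scalar current in pA.
#' @export
receptor_current <- function(occupancy, scheme, v = -70, Erev = 0) {
  w <- scheme$open_conductance[paste0("O", 1:4)]
  if (is.data.frame(occupancy)) {
    po <- as.matrix(occupancy[, paste0("O", 1:4)]) %*% w
    tibble::tibble(time_ms = occupancy$time_ms,
                   current_pA = scheme$g_max * as.numeric(po) * (v - Erev))
  } else {
    po <- sum(occupancy[paste0("O", 1:4)] * w)
    scheme$g_max * po * (v - Erev)
  }
}

#' Steady-state dose–response curve
#'
#' Equilibrium current as a function of glutamate concentration.  The curve
#' of the shipped default scheme is bell-shaped: occupancy of one or two
#' binding sites favors open states, while three or four favor the deep
#' desensitized states, so current peaks at an interior concentration
#' (~32 µM) and falls again toward 1 mM.
#'
#' @param scheme A [rate_scheme()].
#' @param conc_grid Positive, sorted concentrations in µM.
#' @param v,Erev Voltage parameters (mV).
#' @return A tibble `conc_uM`, `current_pA`, `p_open`, with attribute
#'   `peak_uM` holding the grid concentration of maximal current magnitude.
#' @examples
#' dr <- dose_response(default_rate_scheme(), logspace_grid(1, 1000, 121))
#' attr(dr, "peak_uM")
#' @export
dose_response <- function(scheme, conc_grid, v = -70, Erev = 0) {
  if (any(diff(conc_grid) <= 0) || any(conc_grid <= 0)) {
    stop("conc_grid must be positive and strictly increasing", call. = FALSE)
  }
  w <- scheme$open_conductance[paste0("O", 1:4)]
  p_open <- vapply(conc_grid, function(cc) {
    eq <- equilibrium_occupancy(scheme, cc)
    sum(eq[paste0("O", 1:4)] * w)
  }, numeric(1))
  out <- tibble::tibble(conc_uM = conc_grid,
                        current_pA = scheme$g_max * p_open * (v - Erev),
                        p_open = p_open)
  attr(out, "peak_uM") <- conc_grid[which.max(abs(out$current_pA))]
  out
}

#' Logarithmically spaced concentration grid
#'
#' @param from,to Grid limits (µM, positive).
#' @param n Number of points.
#' @return Numeric vector of `n` log-spaced concentrations.
#' @export
logspace_grid <- function(from, to, n = 121) {
  exp(seq(log(from), log(to), length.out = n))
}
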