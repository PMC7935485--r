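#' Specification of one synthetic cell
#'
#' Ground-truth forward-model parameters for a simulated whole-cell
#' recording, plus the fold-changes applied in the paired transporter-block
#' condition and the recording-chain emulation settings (sampling rate,
#' analysis filter, noise level, artifact gaps, leak).  Population defaults
#' follow the fitted cohort this package emulates: ambient 4.7 µM in
#' control, block folds 2.4 (ambient), 2.3 (released glutamate) and an
#' optional conductance fold; release–receptor distance 1.23 µm.
#'
#' @param ambient Control ambient glutamate, µM.
#' @param M Molecules released per event.
#' @param r Release–receptor distance, µm.
#' @param g_max Maximal conductance, nS.
#' @param leak_offset Leak current, pA.
#' @param ambient_fold,M_fold,gmax_fold Block-condition fold-changes (> 0).
#' @param noise_sd Recording noise s.d. in pA *after* the 1 kHz analysis
#'   filter (default 2).
#' @param sampling_khz Acquisition sampling rate, kHz (default 20).
#' @param filter_cutoff Analysis low-pass cutoff, Hz (default 1000).
#' @param artifact_ms Duration of the stimulation artifact after each
#'   stimulus, ms.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(ambient = 4.7, M = 5e6, r = 1.23,
                                g_max = 5, leak_offset = -10,
                                ambient_fold = 2.4, M_fold = 2.3,
                                gmax_fold = 1, noise_sd = 2,
                                sampling_khz = 20, filter_cutoff = 1000,
                                artifact_ms = 1, seed = 1) {
  if (ambient_fold <= 0 || M_fold <= 0 || gmax_fold <= 0) {
    stop("fold-changes must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(ambient = ambient, M = M, r = r, g_max = g_max,
                 leak_offset = leak_offset, ambient_fold = ambient_fold,
                 M_fold = M_fold, gmax_fold = gmax_fold,
                 noise_sd = noise_sd, sampling_khz = sampling_khz,
                 filter_cutoff = filter_cutoff, artifact_ms = artifact_ms,
                 seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

# run expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) {
        rm(list = ".Random.seed", envir = .GlobalEnv)
      }
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a paired control/block synthetic recording
#'
#' Forward-simulates the AMPAR current for the control parameters and for
#' the block condition (`ambient`, `M`, `g_max` multiplied by their folds),
#' then emulates the recording chain: additive white Gaussian noise at the
#' acquisition rate (scaled so its s.d. *after* the zero-phase analysis
#' filter equals `noise_sd`), a constant leak offset, and a large
#' stimulation-artifact deflection for `artifact_ms` after every stimulus.
#' Deterministic per `spec$seed`; the ground truth travels with the data.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param train Stimulus event times, ms.
#' @param scheme A [rate_scheme()] (Q10-scaled to the recording temperature).
#' @param duration_ms Trace duration (default: 400 ms past the last event).
#' @param v,Erev Voltage parameters, mV.
#' @param alpha,D,lam Extracellular diffusion constants.
#' @return A list with trace tibbles `control` and `block`, matching
#'   noiseless traces `control_clean`/`block_clean`, the blanking windows
#'   `artifact_windows`, and a `truth` tibble of ground-truth parameters
#'   per condition.
#' @export
generate_recording <- function(spec, train, scheme,
                               duration_ms = NULL, v = -70, Erev = 0,
                               alpha = 0.21, D = 0.33, lam = 1.55) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  events <- if (inherits(train, "stim_train")) train$event_times
            else as.numeric(train)
  if (is.null(duration_ms)) duration_ms <- max(events) + 400
  dt <- 1 / spec$sampling_khz
  tgrid <- seq(0, duration_ms, by = dt)
  fs_hz <- spec$sampling_khz * 1000

  one <- function(ambient, M, g_max) {
    tp <- transient_params(M = M, r = spec$r, alpha = alpha, D = D,
                           lam = lam, ambient = ambient)
    sch <- scheme
    sch$g_max <- g_max
    simulate_current(sch, tp, events, tgrid, v = v, Erev = Erev,
                     leak_offset = spec$leak_offset, glu_rtol = 1e-4)
  }
  clean_c <- one(spec$ambient, spec$M, spec$g_max)
  clean_b <- one(spec$ambient * spec$ambient_fold, spec$M * spec$M_fold,
                 spec$g_max * spec$gmax_fold)

  sd_acq <- if (spec$noise_sd > 0) {
    spec$noise_sd / filtfilt_noise_sd_factor(fs_hz, spec$filter_cutoff)
  } else 0
  noisy <- .with_seed(spec$seed, {
    lapply(list(clean_c, clean_b), function(tr) {
      y <- tr$current_pA + stats::rnorm(nrow(tr), 0, sd_acq)
      for (t0 in events) {   # saturating stimulation artifact
        idx <- tr$time_ms >= t0 & tr$time_ms < t0 + spec$artifact_ms
        y[idx] <- y[idx] + 2000 * exp(-(tr$time_ms[idx] - t0) /
                                        (spec$artifact_ms / 3))
      }
      tibble::tibble(time_ms = tr$time_ms, current_pA = y)
    })
  })
  windows <- cbind(events - dt / 2, events + spec$artifact_ms + dt / 2)
  truth <- tibble::tibble(
    condition = c("control", "eaat_block"),
    ambient = c(spec$ambient, spec$ambient * spec$ambient_fold),
    M = c(spec$M, spec$M * spec$M_fold),
    r = spec$r,
    g_max = c(spec$g_max, spec$g_max * spec$gmax_fold),
    leak_offset = spec$leak_offset,
    seed = spec$seed
  )
  list(control = noisy[[1]], block = noisy[[2]],
       control_clean = clean_c, block_clean = clean_b,
       artifact_windows = windows, truth = truth)
}

#' Generate a cohort of synthetic cell specifications
#'
#' Per-cell ground-truth parameters are drawn from log-normal distributions
#' centered (in mean) on the population values; the leak offset is normal.
#' Per-cell seeds are drawn from the cohort seed, so the whole cohort is
#' reproducible and distinct seeds give distinct cohorts.
#'
#' @param n_cells Number of cells (>= 1).
#' @param centers Named list of population means
#'   (`ambient`, `M`, `r`, `g_max`, `leak_offset`).
#' @param sdlog Log-scale s.d. of the parameter distributions (scalar or
#'   named like `centers`); 0 gives every cell the center spec.
#' @param leak_sd Normal s.d. of the leak offset, pA.
#' @param seed Cohort seed.
#' @param ... Further arguments (folds, noise, sampling) passed to
#'   [synthetic_cell_spec()] for every cell.
#' @return A tibble with one row per cell (`cell`, parameter columns,
#'   `seed`) and a list-column `spec` of `synthetic_cell_spec` objects.
#' @export
generate_cohort <- function(n_cells,
                            centers = list(ambient = 4.7, M = 5e6,
                                           r = 1.23, g_max = 5,
                                           leak_offset = -10),
                            sdlog = 0.25, leak_sd = 3, seed = 1, ...) {
  stopifnot(n_cells >= 1)
  pos_pars <- c("ambient", "M", "r", "g_max")
  if (length(sdlog) == 1) {
    sdlog <- stats::setNames(rep(sdlog, length(pos_pars)), pos_pars)
  }
  .with_seed(seed, {
    draws <- lapply(pos_pars, function(nm) {
      # exp(-s^2/2) correction makes the population *mean* equal the center
      centers[[nm]] * exp(stats::rnorm(n_cells, 0, sdlog[[nm]]) -
                            sdlog[[nm]]^2 / 2)
    })
    names(draws) <- pos_pars
    leak <- stats::rnorm(n_cells, centers$leak_offset, leak_sd)
    cell_seeds <- sample.int(.Machine$integer.max - 1, n_cells)
    specs <- lapply(seq_len(n_cells), function(i) {
      synthetic_cell_spec(ambient = draws$ambient[i], M = draws$M[i],
                          r = draws$r[i], g_max = draws$g_max[i],
                          leak_offset = leak[i], seed = cell_seeds[i], ...)
    })
    tibble::tibble(cell = seq_len(n_cells),
                   ambient = draws$ambient, M = draws$M, r = draws$r,
                   g_max = draws$g_max, leak_offset = leak,
                   seed = cell_seeds, spec = specs)
  })
}

#' Generate synthetic spike times locked to the modulation cycle
#'
#' An inhomogeneous Poisson process over the modulated segment whose rate is
#' `baseline + onset_gain * bump(theta - 90) + offset_gain *
#' bump(theta - offset_phase_deg)`, with von-Mises-shaped bumps
#' (`exp(kappa*(cos(delta)-1))`, peak 1).  Emulates onset firing at the
#' peak stimulus rate and an offset response whose phase is controllable —
#' the structure the PSTH phase analysis is designed to recover.
#'
#' @param spec A [stimulus_spec()].
#' @param onset_gain Peak onset-component rate, spikes/s (>= 0).
#' @param offset_gain Peak offset-component rate, spikes/s (>= 0).
#' @param offset_phase_deg Center of the offset component, degrees.
#' @param baseline_rate Background rate, spikes/s.
#' @param kappa Bump concentration (larger = narrower; default 0.5, a broad
#'   quasi-sinusoidal bump with half-width ~48°).
#' @param n_sweeps Number of independent sweeps.
#' @param seed Integer seed.
#' @return A tibble `sweep`, `time_ms` (ms from the start of the modulated
#'   segment), sorted within sweep.
#' @export
generate_spike_response <- function(spec, onset_gain = 0, offset_gain = 30,
                                    offset_phase_deg = 206,
                                    baseline_rate = 2, kappa = 0.5,
                                    n_sweeps = 1, seed = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (onset_gain < 0 || offset_gain < 0 || baseline_rate < 0) {
    stop("gains and baseline must be nonnegative", call. = FALSE)
  }
  seg_ms <- spec$modulated_s * 1000
  rate_fun <- function(t_ms) {   # spikes/s
    th <- stimulus_phase_deg(t_ms, spec$f_mod)
    bump <- function(center) exp(kappa * (cos((th - center) * pi / 180) - 1))
    baseline_rate + onset_gain * bump(90) + offset_gain * bump(offset_phase_deg)
  }
  rmax <- baseline_rate + onset_gain + offset_gain
  .with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(sw) {
      if (rmax == 0) return(numeric(0))
      n <- stats::rpois(1, rmax * seg_ms / 1000)
      tt <- sort(stats::runif(n, 0, seg_ms))
      keep <- stats::runif(n) < rate_fun(tt) / rmax
      tt[keep]
    })
    tibble::tibble(
      sweep = rep(seq_len(n_sweeps), lengths(sweeps)),
      time_ms = unlist(sweeps)
    )
  })
}
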