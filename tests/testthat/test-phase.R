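test_that("phase convention puts the peak stimulus rate at 90 degrees", {
  f <- 1
  expect_equal(stimulus_phase_deg(0, f), 90)
  expect_equal(stimulus_phase_deg(250, f), 180)   # quarter cycle later
  expect_equal(stimulus_phase_deg(500, f), 270)   # slowest rate
  expect_equal(stimulus_phase_deg(1000, f), 90)   # next cycle
})

test_that("PSTH folds spikes by cycle and conserves their count", {
  spec <- stimulus_spec(f_mod = 1)
  # deterministic uniform spikes (one per degree of phase): exactly flat
  spacing <- 1000 / 360
  spikes <- seq(spacing / 2, 10000, by = spacing)
  psth <- build_psth(spikes, spec, bin_deg = 10)
  expect_equal(sum(psth$count), length(spikes))
  expect_true(all(psth$count == psth$count[1]))
  # rate normalization: 360 spikes/s of drive spread over 10 cycles
  expect_equal(mean(psth$rate_hz), length(spikes) / 10, tolerance = 1e-9)
  # spikes at the stimulus-rate peak land in the bin containing 90 deg
  at_peak <- seq(0, 9000, by = 1000)  # cycle starts = phase 90
  p2 <- build_psth(at_peak, spec, bin_deg = 10)
  expect_equal(sum(p2$count > 0), 1)
  occupied <- p2$bin_center_deg[p2$count > 0]
  expect_lte(abs(occupied - 90), 5)
  # spikes outside the modulated segment are dropped
  p3 <- build_psth(c(-5, 20, 10500), spec)
  expect_equal(sum(p3$count), 1)
})

test_that("an onset+offset spike pattern yields a two-peaked PSTH", {
  spec <- stimulus_spec(f_mod = 1)
  spikes <- generate_spike_response(spec, onset_gain = 40, offset_gain = 40,
                                    offset_phase_deg = 206,
                                    baseline_rate = 1, kappa = 8,
                                    n_sweeps = 30, seed = 5)
  psth <- build_psth(spikes, spec)
  r <- psth$rate_hz
  thr <- min(r) + 0.5 * (max(r) - min(r))
  # two distinct above-half-max regions
  runs <- rle(r > thr)
  expect_equal(sum(runs$values), 2)
})

test_that("sine fitting recovers generated cycles-per-period and phase", {
  spec <- stimulus_spec(f_mod = 1)
  theta <- seq(5, 355, by = 10)
  # noiseless 2-cycle PSTH
  mk <- function(rate) {
    out <- tibble::tibble(bin_center_deg = theta, count = 0, rate_hz = rate)
    class(out) <- c("glu_psth", class(out))
    attr(out, "bin_deg") <- 10
    out
  }
  fit2 <- fit_sine(mk(20 + 8 * sin(2 * pi * 2 * theta / 360 + 0.7)))
  expect_equal(fit2$cycles_per_period, 2, tolerance = 0.005)
  expect_equal(fit2$amplitude, 8, tolerance = 0.01)
  # noiseless 1-cycle PSTH peaked at 270 deg:
  # sin(2*pi*theta/360 + phi0) maximal at 270 => phi0 = 180 deg
  fit1 <- fit_sine(mk(10 + 5 * sin(2 * pi * theta / 360 + pi)))
  expect_equal(fit1$cycles_per_period, 1, tolerance = 0.005)
  expect_equal(as.numeric(offset_peak_phase(fit1)), 270, tolerance = 1)
  # flat PSTH: flagged degenerate, amplitude ~ 0
  fitf <- fit_sine(mk(rep(7, length(theta))))
  expect_true(fitf$degenerate)
  expect_lt(fitf$amplitude, 1e-6)
})

test_that("sine fit is stable under bin-width halving", {
  spec <- stimulus_spec(f_mod = 1)
  spikes <- generate_spike_response(spec, offset_gain = 40,
                                    offset_phase_deg = 230,
                                    baseline_rate = 2, n_sweeps = 25,
                                    seed = 9)
  f10 <- fit_sine(build_psth(spikes, spec, bin_deg = 10))
  f5 <- fit_sine(build_psth(spikes, spec, bin_deg = 5))
  expect_equal(f10$cycles_per_period, f5$cycles_per_period, tolerance = 0.1)
  expect_equal(as.numeric(offset_peak_phase(f10)),
               as.numeric(offset_peak_phase(f5)), tolerance = 5)
})

test_that("phase shifts convert to delays linearly and inversely in f_mod", {
  expect_equal(phase_to_delay(77, 1), 213.9, tolerance = 0.05)
  expect_equal(phase_to_delay(360, 1), 1000)
  expect_equal(phase_to_delay(90, 3), 83.3, tolerance = 0.05)
  expect_equal(phase_to_delay(2 * 77, 1), 2 * phase_to_delay(77, 1))
  expect_equal(phase_to_delay(77, 2), phase_to_delay(77, 1) / 2)
  expect_error(phase_to_delay(77, 0), "positive")
})
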