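test_that("noise-free recordings equal the forward model away from artifacts", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(noise_sd = 0, seed = 2)
  rec <- generate_recording(cs, train, sch)
  w <- rec$artifact_windows
  in_artifact <- Reduce(`|`, lapply(seq_len(nrow(w)), function(k) {
    rec$control$time_ms >= w[k, 1] & rec$control$time_ms <= w[k, 2]
  }))
  expect_identical(rec$control$current_pA[!in_artifact],
                   rec$control_clean$current_pA[!in_artifact])
  # artifacts are large positive deflections at each stimulus
  expect_gt(max(rec$control$current_pA[in_artifact]), 1000)
  # ground truth travels with the data
  expect_equal(rec$truth$ambient, c(4.7, 4.7 * 2.4))
  expect_equal(rec$truth$M[2] / rec$truth$M[1], 2.3)
})

test_that("recordings are seed-deterministic", {
  sch <- warm_scheme()
  train <- short_train()
  r1 <- generate_recording(synthetic_cell_spec(seed = 77), train, sch)
  r2 <- generate_recording(synthetic_cell_spec(seed = 77), train, sch)
  r3 <- generate_recording(synthetic_cell_spec(seed = 78), train, sch)
  expect_identical(r1$control$current_pA, r2$control$current_pA)
  expect_false(identical(r1$control$current_pA, r3$control$current_pA))
})

test_that("post-filter residual noise matches the requested noise_sd", {
  sch <- warm_scheme()
  train <- constant_train(50, n = 3, start_ms = 10)
  sds <- vapply(1:5, function(s) {
    cs <- synthetic_cell_spec(noise_sd = 2, seed = 100 + s)
    rec <- generate_recording(cs, train, sch, duration_ms = 300)
    prep <- preprocess_trace(rec$control, rec$artifact_windows)
    clean <- preprocess_trace(rec$control_clean, rec$artifact_windows)
    stats::sd(prep$current_pA - clean$current_pA)
  }, numeric(1))
  expect_equal(mean(sds), 2, tolerance = 0.1)
})

test_that("cohorts are reproducible with means centered on the population", {
  # zero-variance cohort of one: exactly the center spec
  c1 <- generate_cohort(1, sdlog = 0, leak_sd = 0, seed = 5)
  expect_equal(c1$ambient, 4.7)
  expect_equal(c1$M, 5e6)
  expect_equal(c1$r, 1.23)
  expect_equal(c1$leak_offset, -10)
  # law of large numbers: cohort mean ambient near the center at n = 200
  big <- generate_cohort(200, sdlog = 0.25, seed = 6)
  expect_equal(mean(big$ambient), 4.7, tolerance = 0.03)
  expect_equal(mean(big$M), 5e6, tolerance = 0.03)
  # reproducible; distinct seeds give distinct cohorts
  expect_identical(generate_cohort(5, seed = 9)$ambient,
                   generate_cohort(5, seed = 9)$ambient)
  expect_false(identical(generate_cohort(5, seed = 9)$ambient,
                         generate_cohort(5, seed = 10)$ambient))
})

test_that("synthetic spike trains follow the requested cycle-locked rate", {
  spec <- stimulus_spec(f_mod = 1)
  # zero gains: homogeneous Poisson at the baseline rate
  hom <- generate_spike_response(spec, onset_gain = 0, offset_gain = 0,
                                 baseline_rate = 20, n_sweeps = 4, seed = 3)
  n <- nrow(hom)
  expect_lt(abs(n - 20 * 10 * 4), 4 * sqrt(20 * 10 * 4))  # within 4 sd
  # uniform phase distribution
  psth <- build_psth(hom, spec)
  expect_equal(mean(psth$rate_hz), 20, tolerance = 0.15)
  # doubling all gains doubles the expected spike count
  lo <- generate_spike_response(spec, onset_gain = 10, offset_gain = 10,
                                baseline_rate = 5, n_sweeps = 20, seed = 4)
  hi <- generate_spike_response(spec, onset_gain = 20, offset_gain = 20,
                                baseline_rate = 10, n_sweeps = 20, seed = 4)
  expect_equal(nrow(hi) / nrow(lo), 2, tolerance = 0.15)
  # determinism
  expect_identical(
    generate_spike_response(spec, seed = 6),
    generate_spike_response(spec, seed = 6))
})

test_that("offset-response phase survives the full generate-analyze loop", {
  spec <- stimulus_spec(f_mod = 1)
  spikes <- generate_spike_response(spec, offset_gain = 60,
                                    offset_phase_deg = 206,
                                    baseline_rate = 2, n_sweeps = 40,
                                    seed = 14)
  fit <- fit_sine(build_psth(spikes, spec))
  expect_equal(as.numeric(offset_peak_phase(fit)), 206, tolerance = 5)
})
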