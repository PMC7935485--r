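test_that("preprocessing averages, blanks artifacts and low-pass filters", {
  t <- seq(0, 100, by = 0.05)
  base <- tibble::tibble(time_ms = t, current_pA = -20 + 5 * sin(t / 8))
  # averaging identical traces changes nothing
  avg <- preprocess_trace(list(base, base, base), filter_cutoff = NULL)
  expect_equal(avg$current_pA, base$current_pA)
  # a DC trace passes the zero-phase filter unchanged
  dc <- tibble::tibble(time_ms = t, current_pA = rep(-33, length(t)))
  expect_equal(preprocess_trace(dc)$current_pA, dc$current_pA,
               tolerance = 1e-6)
  # a one-sample spike inside an artifact window is removed by interpolation
  spiked <- base
  spiked$current_pA[t == 50] <- 4000
  clean <- preprocess_trace(spiked, artifact_windows = rbind(c(49, 51)),
                            filter_cutoff = NULL)
  expect_lt(max(abs(clean$current_pA - base$current_pA)), 0.1)
  # malformed windows are rejected
  expect_error(preprocess_trace(base, rbind(c(51, 49))), "end <= start")
  expect_error(preprocess_trace(base, rbind(c(10, 20), c(15, 30))),
               "overlap")
})

test_that("simulated current reproduces the hallmark synaptic phenomena", {
  sch <- warm_scheme()
  tg <- seq(0, 600, by = 0.25)
  train <- short_train()
  # no ambient, no events: flat leak
  flat <- simulate_current(sch, transient_params(M = 5e6, r = 1.23),
                           numeric(0), tg, leak_offset = -12)
  expect_equal(flat$current_pA, rep(-12, length(tg)), tolerance = 1e-9)
  # ambient glutamate tonically desensitizes: smaller first fast EPSC
  with_amb <- simulate_current(sch, transient_params(5e6, 1.23, ambient = 4.7),
                               train, tg)
  no_amb <- simulate_current(sch, transient_params(5e6, 1.23, ambient = 0),
                             train, tg)
  first_peak <- function(tr) {
    w <- tr$time_ms >= 20 & tr$time_ms < 40
    min(tr$current_pA[w]) - tr$current_pA[1]
  }
  expect_gt(first_peak(with_amb), first_peak(no_amb))  # less negative
  # slow EPSC: after the train ends (200 ms) the current rises to a late
  # peak as glutamate decays through the dose-response maximum, then decays
  # over hundreds of ms
  tg2 <- seq(0, 2000, by = 0.5)
  long <- simulate_current(sch, transient_params(5e6, 1.23, ambient = 4.7),
                           train, tg2)
  tail_idx <- tg2 > 220
  t_peak <- tg2[tail_idx][which.max(abs(long$current_pA[tail_idx]))]
  expect_gt(t_peak, 250)
  expect_lt(t_peak, 900)
  i_at <- function(t) abs(long$current_pA[match(t, tg2)])
  expect_gt(i_at(t_peak), i_at(0))         # outlasts the tonic level
  expect_lt(i_at(2000), 0.8 * i_at(t_peak))  # hyperbolic-tail decay
  after <- abs(long$current_pA[tg2 > t_peak])
  expect_true(all(diff(after) < 1e-6))
})

test_that("noise-free self-consistency: the fit recovers known parameters", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(ambient = 4.7, M = 5e6, r = 1.23, g_max = 5,
                            leak_offset = -10, noise_sd = 0, seed = 1)
  rec <- generate_recording(cs, train, sch)
  prep <- downsample4k(preprocess_trace(rec$control, rec$artifact_windows))
  truth <- c(M = 5e6, r = 1.23, ambient = 4.7, g_max = 5, leak_offset = -10)
  spec <- fit_spec(init = truth, max_evals = 200, restarts = 0, seed = 3)
  fit <- fit_control(prep, train, sch, spec = spec, glu_rtol = 2e-3,
                     exclude_windows = rec$artifact_windows)
  expect_lt(fit$objective, 0.05)  # pA^2; essentially zero
  expect_true(all(abs(fit$par[names(truth)] - truth) / truth < 0.01))
})

test_that("fits are deterministic given seed, spec and data", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(seed = 8)
  rec <- generate_recording(cs, train, sch)
  prep <- downsample4k(preprocess_trace(rec$control, rec$artifact_windows))
  spec <- fit_spec(max_evals = 30, restarts = 1, seed = 21)
  f1 <- fit_control(prep, train, sch, spec = spec)
  f2 <- fit_control(prep, train, sch, spec = spec)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
})

test_that("objective is invariant to time origin and stable under resampling", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(seed = 12)
  rec <- generate_recording(cs, train, sch)
  prep <- downsample4k(preprocess_trace(rec$control, rec$artifact_windows))
  par <- c(M = 5e6, r = 1.23, ambient = 4.7, g_max = 5, leak_offset = -10)
  w <- rec$artifact_windows
  o0 <- fit_objective(par, prep, train, sch, exclude_windows = w)
  # shift every time stamp (data, train and windows) by +500 ms
  shifted <- dplyr::mutate(prep, time_ms = time_ms + 500)
  os <- fit_objective(par, shifted, train$event_times + 500, sch,
                      exclude_windows = w + 500)
  expect_equal(os, o0, tolerance = 1e-8)
  # mean-squared objective changes <1% when resampling within the filter band
  # (the 20 kHz recording decimated by 5 vs by 3)
  alt <- preprocess_trace(rec$control, w)[seq(1, 12001, by = 3), ]
  oh <- fit_objective(par, alt, train, sch, exclude_windows = w)
  expect_lt(abs(oh - o0) / o0, 0.01)
})

test_that("error reduction compares nested fits", {
  expect_equal(error_reduction(2, 2), 0)
  expect_equal(error_reduction(1, 2), 50)
  expect_error(error_reduction(1, 0), "zero")
})

test_that("the block refit inherits frozen parameters from control", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(seed = 31)
  rec <- generate_recording(cs, train, sch)
  prep <- downsample4k(preprocess_trace(rec$control, rec$artifact_windows))
  spec <- fit_spec(max_evals = 40, restarts = 0, seed = 2)
  ctrl <- fit_control(prep, train, sch, spec = spec)
  # identical control/block data: fold changes ~ 1
  blk <- fit_eaat_block(prep, train, sch, ctrl)
  expect_setequal(blk$free, c("ambient", "M"))
  expect_equal(blk$par[["r"]], ctrl$par[["r"]])       # frozen
  expect_equal(blk$par[["g_max"]], ctrl$par[["g_max"]])
  expect_equal(blk$par[["ambient"]] / ctrl$par[["ambient"]], 1,
               tolerance = 0.05)
  expect_equal(blk$par[["M"]] / ctrl$par[["M"]], 1, tolerance = 0.05)
  expect_error(fit_eaat_block(prep, train, sch, control_fit = NULL),
               "paired control")
})

test_that("tidy and glance summarize fit objects", {
  sch <- warm_scheme()
  train <- short_train()
  cs <- synthetic_cell_spec(seed = 4)
  rec <- generate_recording(cs, train, sch)
  prep <- downsample4k(preprocess_trace(rec$control, rec$artifact_windows))
  fit <- fit_control(prep, train, sch,
                     spec = fit_spec(max_evals = 25, restarts = 1, seed = 1))
  td <- tidy(fit)
  expect_setequal(td$term, c("M", "r", "ambient", "g_max", "leak_offset"))
  expect_true(all(td$free))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(prep))
  expect_equal(gl$rmse, sqrt(gl$objective))
  expect_s3_class(autoplot(fit), "ggplot")
})
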