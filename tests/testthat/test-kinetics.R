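test_that("equilibrium occupancy matches a dense linear-solve oracle", {
  sch <- ref_scheme()
  # no glutamate: everything in C0
  eq0 <- equilibrium_occupancy(sch, 0)
  expect_equal(unname(eq0[["C0"]]), 1, tolerance = 1e-10)
  for (glu in c(0.5, 5, 32, 320)) {
    expect_equal(equilibrium_occupancy(sch, glu),
                 equilibrium_oracle(sch, glu), tolerance = 1e-9)
  }
})

test_that("unliganded fraction at the resting ambient level is ~54%", {
  eq <- equilibrium_occupancy(ref_scheme(), 5)
  expect_equal(unname(eq[["C0"]]), 0.542, tolerance = 1e-4)
})

test_that("propagation at fixed concentration relaxes to equilibrium", {
  sch <- ref_scheme()
  for (glu in c(0, 2, 30, 300)) {
    tr <- tibble::tibble(time_ms = seq(0, 4000, by = 1), glu_uM = glu)
    occ <- propagate(sch, tr, initial = equilibrium_occupancy(sch, 0))
    final <- unlist(occ[nrow(occ), ampar_states])
    expect_lt(max(abs(final - equilibrium_occupancy(sch, glu))), 1e-6)
  }
  # and with no glutamate from all-C0 the occupancy never moves
  tr0 <- tibble::tibble(time_ms = 0:100, glu_uM = 0)
  occ0 <- propagate(sch, tr0, initial = equilibrium_occupancy(sch, 0))
  expect_lt(max(abs(occ0$C0 - 1)), 1e-12)
})

test_that("propagation conserves probability on random concentration traces", {
  sch <- warm_scheme()
  set.seed(11)
  for (rep in 1:5) {
    conc <- exp(stats::runif(400, log(0.1), log(2000)))
    occ <- propagate(sch, conc, dt_ms = 0.2,
                     initial = equilibrium_occupancy(sch, conc[1]))
    sums <- rowSums(occ[, ampar_states])
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_gte(min(as.matrix(occ[, ampar_states])), 0)
  }
})

test_that("matrix-exponential and adaptive-ODE paths agree on a step protocol", {
  sch <- ref_scheme()
  conc <- c(rep(0, 50), rep(1000, 200), rep(5, 500))
  tr <- tibble::tibble(time_ms = (seq_along(conc) - 1) * 0.1, glu_uM = conc)
  init <- equilibrium_occupancy(sch, 0)
  occ_expm <- propagate(sch, tr, initial = init, method = "expm")
  occ_ode <- propagate(sch, tr, initial = init, method = "ode",
                       rtol = 1e-10, atol = 1e-12)
  dmax <- max(abs(as.matrix(occ_expm[, ampar_states]) -
                    as.matrix(occ_ode[, ampar_states])))
  expect_lt(dmax, 1e-5)
})

test_that("current computation is the conductance-weighted driving force", {
  sch <- ref_scheme()
  # occupancy engineered so total open conductance is exactly 1 nS
  occ <- stats::setNames(rep(0, 13), ampar_states)
  occ["O1"] <- 1 / sch$g_max / sch$open_conductance[["O1"]]
  occ["C0"] <- 1 - occ["O1"]
  expect_equal(receptor_current(occ, sch, v = -70, Erev = 0), -70)
  # all occupancy closed/desensitized: zero current
  shut <- stats::setNames(rep(0, 13), ampar_states)
  shut["C0"] <- 0.5; shut["D3"] <- 0.5
  expect_identical(receptor_current(shut, sch), 0)
  # linear in g_max
  half <- sch; half$g_max <- sch$g_max / 2
  expect_equal(receptor_current(occ, half), receptor_current(occ, sch) / 2)
})

test_that("dose-response is bell-shaped with its peak at 32 uM", {
  sch <- ref_scheme()
  dr <- dose_response(sch, logspace_grid(1, 1000, 301))
  peak <- attr(dr, "peak_uM")
  expect_equal(peak, 32, tolerance = 0.05)
  # falls from 1 mM toward the interior peak
  expect_lt(abs(dr$current_pA[nrow(dr)]), max(abs(dr$current_pA)))
  # unique interior maximum: |current| increases then decreases once
  s <- sign(diff(abs(dr$current_pA)))
  expect_equal(sum(diff(s[s != 0]) != 0), 1)
})

test_that("uniform Q10 scaling leaves the equilibrium dose-response unchanged", {
  sch <- ref_scheme()
  warm <- scale_rates_q10(sch, 34)
  grid <- logspace_grid(1, 1000, 61)
  dr1 <- dose_response(sch, grid)
  dr2 <- dose_response(warm, grid)
  expect_equal(dr2$current_pA, dr1$current_pA, tolerance = 1e-9)
  # while relaxation speeds scale by the common factor: compare slowest
  # relaxation eigenvalues at a fixed concentration
  ev1 <- sort(Re(eigen(generator_matrix(sch, 10))$values), decreasing = TRUE)
  ev2 <- sort(Re(eigen(generator_matrix(warm, 10))$values), decreasing = TRUE)
  expect_equal(ev2[2] / ev1[2], 2.4^1.1, tolerance = 1e-8)
})
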