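# shared fixtures, built in code at test time

# scheme at the reference temperature (23 C)
ref_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- default_rate_scheme()
    sch
  }
})

# scheme Q10-scaled to the recording temperature (34 C)
warm_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- scale_rates_q10(default_rate_scheme(), 34)
    sch
  }
})

# short 50 Hz x 10 protocol used throughout the fitting tests
short_train <- function() constant_train(50, n = 10, start_ms = 20)

# independent equilibrium oracle: dense linear solve of Q p = 0, sum(p) = 1
# (replaces one row of the generator by the normalization constraint; a
# different route than the SVD null space used by the implementation)
equilibrium_oracle <- function(scheme, glu) {
  Q <- generator_matrix(scheme, glu)
  A <- rbind(Q[-1, ], rep(1, ncol(Q)))
  stats::setNames(solve(A, c(rep(0, nrow(Q) - 1), 1)), ampar_states)
}

# downsample a 20 kHz preprocessed trace to 4 kHz for fitting
downsample4k <- function(trace) trace[seq(1, nrow(trace), by = 5), ]
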