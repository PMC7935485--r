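# ambientglu

Inference of ambient and evoked glutamate at the mossy-fiber → unipolar
brush cell (UBC) synapse from AMPA-receptor kinetics.

UBCs receive a single giant mossy-fiber synapse whose enclosed geometry
lets glutamate pool and linger. Excitatory amino acid transporters (EAATs)
determine both how much transmitter reaches the receptors after each
release and how much *ambient* glutamate stands in the cleft between
releases — neither is directly measurable. `ambientglu` infers both by
least-squares fitting a biophysical forward model to whole-cell AMPAR
current recordings, and provides the stimulus-generation and spike-phase
analysis used to study how transporters shape spike timing.

The forward model couples two pieces:

* a **13-state AMPAR kinetic scheme** — closed states C0–C4 (0–4 glutamates
  bound) with an open (O1–O4) and a desensitized (D1–D4) state on each
  liganded level — propagated by the master equation `dp/dt = Q(c(t)) p`,
  with current `I = g_max · Σ_k w_k P(O_k) · (v − Erev)`. Uniform Q10
  temperature scaling (2.4) maps the 23 °C rate table to recording
  temperature. The scheme's bell-shaped steady-state dose–response
  (peak ≈ 32 µM) and tonic desensitization by micromolar ambient glutamate
  are what make the inference work;
* a **3D point-source diffusion transient** in tortuous extracellular
  space, `C(τ) = M / (8α (π D_eff τ)^{3/2}) · exp(−r²/(4 D_eff τ)) +
  ambient` with `D_eff = D/λ²` (α = 0.21, D = 0.33 µm²/ms, λ = 1.55),
  summed linearly over stimulus trains.

A control fit varies `{M, r, ambient, g_max, leak_offset}`; the paired
EAAT-block trace is then refit varying only `{ambient, M}` (optionally
`g_max`), so transporter block is expressed as fold-changes. A synthetic
data module generates noisy recordings and cycle-locked spike trains with
known ground truth, making the whole pipeline testable end to end; the
stimulus module writes frequency-modulated event-time files
(rate = carrier + depth·cos(2πft)), and the phase module folds spikes into
cycle PSTHs, fits free-frequency sines and converts offset-response phase
shifts into delays.

## Worked example

```r
library(ambientglu)

scheme <- default_rate_scheme()
100 * equilibrium_occupancy(scheme, 5)[["C0"]]    # agonist-free receptors at 5 uM
attr(dose_response(scheme, logspace_grid(1, 1000, 601)), "peak_uM")
phase_to_delay(77, f_mod = 1)                     # offset-phase shift -> delay

# fit a synthetic control recording (50 Hz x 10 stimuli, 34 degC)
warm  <- scale_rates_q10(scheme, 34)
train <- constant_train(50, n = 10, start_ms = 20)
cell  <- synthetic_cell_spec(ambient = 4.7, M = 5e6, r = 1.23, seed = 7)
rec   <- generate_recording(cell, train, warm)
prep  <- preprocess_trace(rec$control, rec$artifact_windows)
prep  <- prep[seq(1, nrow(prep), by = 5), ]       # 4 kHz fitting grid
fit   <- fit_control(prep, train, warm,
                     spec = fit_spec(max_evals = 220, restarts = 1, seed = 1),
                     exclude_windows = rec$artifact_windows)
fit
```

This prints:

```
[1] 54.2
[1] 31.98895
[1] 213.8889
<glu_fit> condition: control | objective (mean sq. residual): 4.039 pA^2
  free: M = 4.883e+06, r = 1.265, ambient = 4.581, g_max = 5.003, leak_offset = -9.887
```

54.2% of receptors are free of agonist at the 5 µM resting ambient level;
the equilibrium dose–response peaks at 32 µM; a 77° offset-phase shift at
1 Hz modulation is a 214 ms delay. The fit recovers the generating
parameters (ambient 4.7 µM, M 5×10⁶, r 1.23 µm, g_max 5 nS, leak −10 pA)
to within a few percent from a 2 pA-noise recording; the residual mean
square ≈ 4 pA² is the noise floor. `tidy(fit)`, `glance(fit)` and
`autoplot(fit)` summarize and plot the result, and
`fit_eaat_block(prep_block, train, warm, fit)` performs the paired
transporter-block refit.

See the vignette (`vignettes/ambient-glutamate-inference.Rmd`) for the
model, calibration, conventions and limitations.

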