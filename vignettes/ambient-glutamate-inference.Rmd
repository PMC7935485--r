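---
title: "Inferring ambient and evoked glutamate from AMPA-receptor kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ambient and evoked glutamate from AMPA-receptor kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambientglu)
```

## The scientific problem

At the giant synapse between a mossy fiber (MF) and a cerebellar unipolar
brush cell (UBC), glutamate is not cleared instantly after release: the
enclosed synaptic geometry lets transmitter pool and linger, and excitatory
amino acid transporters (EAATs) set both how much of each release reaches
the receptors and how much *ambient* glutamate remains standing between
release events. Neither quantity can be measured directly. This package
infers both by fitting a biophysical forward model of the AMPA-receptor
(AMPAR) current to whole-cell recordings: a 13-state receptor kinetic
scheme driven by a diffusion-derived glutamate concentration time course
with an additive ambient floor. The same toolkit generates the
frequency-modulated stimulus trains used to probe spike timing in
near-physiological conditions, and analyzes the resulting spike phase.

## The receptor model

The scheme has five closed states `C0`–`C4` (0–4 glutamate molecules
bound), and an open (`O1`–`O4`) and desensitized (`D1`–`D4`) state attached
to each liganded closed state. Only binding steps `C_i -> C_{i+1}` depend
on concentration; binding-chain statistical factors (4,3,2,1 forward and
1,2,3,4 backward) are written explicitly into the rate table. The state
vector evolves by the master equation `dp/dt = Q(c(t)) p`, where the
generator is affine in the concentration, `Q(c) = Q0 + c Q1`.

Current follows from the open states:

```
g = g_max * sum_k w_k P(O_k),   I = g * (v - Erev)
```

with equal open-state weights `w_k` by default (the data do not constrain a
graded alternative), holding potential `v = -70` mV and reversal
`Erev = 0` mV, so nS × mV gives pA directly.

Two properties of the scheme carry the biology:

* **Tonic desensitization.** A few µM of ambient glutamate drives an
  appreciable fraction of receptors into bound and desensitized states
  before any stimulus, shrinking the first evoked EPSC.
* **A bell-shaped steady-state dose–response.** Entry into the deep
  desensitized states `D3`/`D4` dominates at high occupancy, so the
  equilibrium current peaks at an interior concentration (~32 µM) and falls
  toward 1 mM. As cleft glutamate decays through this peak after a train,
  the model produces the characteristic slow EPSC.

### The shipped rate table and its calibration

Published rate constants for this receptor scheme are not redistributed
with the package, so it ships its own calibrated table (`inst/extdata/ubc_ampar_rates.tsv`, regenerated by
`scripts/calibrate_rate_table.R`). Calibration exploits the fact that the
scheme's graph is a tree (a binding chain with leaves), so its equilibrium
satisfies detailed balance and has a closed form. With per-site
dissociation constant `kd`, shared open/closed equilibrium `E`, and
shallow/deep desensitization equilibria `f` (D1/D2) and `F` (D3/D4), two
targets are imposed *exactly* by solving a 2×2 linear system:

1. the `C0` occupancy at 5 µM glutamate equals 0.542 (the agonist-free
   fraction at the resting ambient level), and
2. the equilibrium dose–response is stationary at exactly 32 µM.

We chose `kd = 120` µM and `E = 0.5`, giving `f = 3.25`, `F = 13.35` and an
equilibrium current at 1 mM that is 41% of the peak value — a pronounced
bell. Absolute rates then set kinetics without touching equilibria: binding
0.02 /ms/µM per site, unbinding 2.4 /ms, channel closing 2 /ms (fast
deactivation), recovery 0.05 /ms from D1/D2 and 0.004 /ms from D3/D4 (slow
recovery, which generates the slow tail current). If the published table is
available it loads verbatim through `load_rate_scheme()`.

```{r dose-response}
scheme <- default_rate_scheme()
dr <- dose_response(scheme, logspace_grid(1, 1000, 301))
attr(dr, "peak_uM")
100 * equilibrium_occupancy(scheme, 5)[["C0"]]
```

### Temperature

Rates are specified at 23 °C and scaled to the recording temperature with a
single Q10 of 2.4 applied to every rate (`scale_rates_q10()`). Because the
factor is uniform it leaves every equilibrium — including the whole
dose–response curve — unchanged and only rescales relaxation speeds; the
default recording temperature in the synthetic experiments is 34 °C
(thermal factor 2.4^1.1 ≈ 2.62).

### Numerics

The reference propagation path computes one 13×13 matrix exponential per
sample of the (piecewise-constant) concentration trace — exact for that
concentration model and unconditionally stable even at 1 mM steps, where
the fastest rates reach hundreds per ms. An adaptive stiff ODE path
(`deSolve::lsoda`) is exposed as a cross-check; the two agree to < 1e-5 on
step protocols, and fixed-concentration propagation matches the SVD
null-space equilibrium to < 1e-6 (both are asserted in the test suite).
During fitting, consecutive samples whose concentration differs by less
than a relative tolerance (`glu_rtol = 0.02`) reuse the previous
exponential; this perturbs the simulated current by ≲ 0.15 pA — an order
of magnitude below the synthetic noise floor — and roughly halves the cost
of an objective evaluation. All propagation enforces probability sums
within 1e-6 and nonnegativity.

## The glutamate field

A release event deposits `M` molecules at a point; the concentration at
distance `r` in tortuous extracellular space is the instantaneous
point-source solution of the 3D diffusion equation scaled by the volume
fraction, plus the ambient floor:

```
C(tau) = M / (8 alpha (pi D_eff tau)^{3/2}) * exp(-r^2 / (4 D_eff tau)) + ambient
D_eff  = D / lambda^2
```

with defaults `alpha = 0.21`, `D = 0.33` µm²/ms, `lambda = 1.55` (the
diffusion coefficient is interpreted in µm²/ms, the standard literature
value for glutamate in extracellular space; internal units are µM, ms, µm
throughout). The kernel's hyperbolic tail is what approximates the slow
exit of glutamate from the enclosed synaptic space. Trains superpose
single-event transients linearly (no presynaptic depression), with the
ambient floor added once. Mass conservation of the kernel is verified by
radial quadrature to < 0.5%. The model deliberately keeps a single release
point and a single detection distance per cell, and contains no uptake
term: transporter manipulations enter only through the fitted `M` and
`ambient`, mirroring the experimental logic.

## Fitting

`fit_control()` minimizes the mean squared residual (pA²) between a
preprocessed recorded trace and the forward simulation, over the trace
minus the blanked artifact windows. Preprocessing mirrors the experimental
chain: trial averaging, artifact blanking by linear interpolation, and
zero-phase 4th-order Butterworth low-pass at 1 kHz — and the *simulated*
current is passed through the identical filter before the residual is
formed, so model and data see the same bandwidth. The initial receptor
state is always the equilibrium at the candidate ambient concentration:
tonic desensitization is part of the model, not a nuisance.

The optimizer is a bounded derivative-free simplex (Nelder–Mead with an
out-of-bounds penalty) on log-transformed positive parameters
(`M`, `r`, `ambient`, `g_max`; the leak offset stays linear), restarted
from jittered starting points; the spread of estimates across restarts is
the only uncertainty surrogate reported. Everything is deterministic given
the `fit_spec()` seed. The free set for a control fit is
`{M, r, ambient, g_max, leak_offset}`; `fit_eaat_block()` then refits the
paired transporter-block trace varying only `{ambient, M}` (optionally also
`g_max`), inheriting everything else frozen from the control fit — the
two-stage protocol that turns paired recordings into fold-changes.
`error_reduction()` quantifies how much the nested addition of the ambient
parameter improves a fit.

**Identifiability.** `M` and `r` covary strongly (a larger release farther
away can mimic a smaller one nearby), which is why fits start from
population-level initial values and why the recovered `r` should be read
as a cohort-level quantity. The ambient level and the leak offset both
shift the baseline, but ambient also controls tonic desensitization and
the slow-current shape, which separates them in practice; the pre-stimulus
baseline segment is retained in the fit window for exactly this reason.

## Stimulus generation and phase analysis

The in-vivo-like protocol is 5 s of silence, 10 s at the 26 Hz carrier,
then 10 s of sinusoidal frequency modulation. The modulated segment is
defined by the phase function

```
phi(t) = 2 pi carrier t + (d / f) sin(2 pi f t)
```

whose derivative — the instantaneous rate — is `carrier + d cos(2 pi f t)`.
This is the unique reading of the protocol under which the "depth" `d` is
the rate excursion in Hz (extrema `carrier ± d`); the convention is stamped
into every train file `fm_train()` writes. The canonical pairs are
`f = 0.3, 1, 3` Hz with `d = 6, 40, 120` Hz. Event times are the first
forward crossings of integer cycles of `phi`; where `d > carrier` the
instantaneous rate is negative, the phase retreats, and no events are
emitted until the phase has re-advanced past its running maximum — so no
cycle ever fires twice. A consequence worth noting: over whole modulation
cycles the long-run event rate equals the carrier (the net phase gain),
not the rectified mean of the rate function, because retreated phase must
be re-gained before new crossings occur.

Spike analysis folds spikes over modulation cycles with the stimulus-rate
peak mapped to 90° and the trough to 270° (`build_psth()`, default 10°
bins; spikes in silent negative-rate intervals are folded like any others).
`fit_sine()` fits `offset + A sin(2 pi n theta/360 + phi0)` with the
cycles-per-period `n` free — the statistic that separates two-peaked
onset+offset responses (`n ≈ 2`) from single-peaked ones (`n ≈ 1`). For
each candidate `n` the amplitude and phase are a linear solve; `n` is found
by grid scan plus golden-section refinement. The offset-response phase is
the maximum of the *fitted* curve within the 90°–360° half (robust to bin
noise); `phase_to_delay()` converts phase shifts to milliseconds.

## Synthetic data: what it emulates, and what it does not

`generate_recording()` emulates averaged whole-cell voltage-clamp traces:
the forward-model current, a constant leak offset, white Gaussian noise at
the 20 kHz acquisition rate scaled so that its s.d. *after* the 1 kHz
analysis filter equals `noise_sd` (default 2 pA, a declared convention —
the recordings' noise spectrum is not characterized, and no 1/f component
is modeled), and a saturating stimulation-artifact deflection after every
stimulus. Ground truth always travels with the data. Cohorts
(`generate_cohort()`) draw per-cell parameters from log-normal
distributions whose *means* equal the population centers (ambient 4.7 µM,
`M` 5×10⁶ molecules, `r` 1.23 µm, `g_max` 5 nS; block folds 2.4 / 2.3 /
1.7-optional; log-s.d. 0.25), with per-cell seeds drawn from the cohort
seed. The release magnitude `M = 5 × 10⁶` molecules is chosen so that
cleft concentration exceeds 1 mM during 50 Hz trains at `r = 1.23` µm and
decays through the 32 µM dose–response peak a few hundred ms after the
train — the regime the slow EPSC lives in.

`generate_spike_response()` produces inhomogeneous-Poisson spikes whose
rate carries an onset component locked to 90° and an offset component at a
controllable phase, with von-Mises-shaped bumps. The default bump
concentration `kappa = 0.5` gives a broad, quasi-sinusoidal response
(half-width ≈ 113°), chosen so the generated offset component lies in the
model class the sine-fit analysis assumes: with narrow bumps (`kappa` ≳ 4)
the free-frequency sine fit systematically displaces the recovered peak by
several degrees (the fit trades frequency against phase to chase a
non-sinusoidal shape) — a property of the analysis worth knowing about
when interpreting fitted phases of sharply peaked PSTHs.

What passing the synthetic tests does **not** show about real data: the
generator contains no series-resistance error, no slow drift or 1/f noise,
no presynaptic depression or stochastic release, no mGluR2/GIRK outward
component, and no spike-threshold dynamics — spikes are drawn from a rate
function, not a neuron model. Recovery performance on this generator is a
consistency check of the inference machinery, not evidence that real
recordings constrain the parameters equally well.

## Problem sizes and experiment design

The cohort experiments in the test suite and acceptance script use 10
synthetic cells (one noise realization each, per-cell seeds from the
cohort seed), the 50 Hz × 10 protocol sampled at 20 kHz for generation and
decimated to 4 kHz for fitting over 0–600 ms, optimizer budgets of 220
evaluations with one jittered restart for control fits, and nested
no-ambient refits on 3 cells. These sizes were chosen as the smallest
cohort that stably exercises the two-stage protocol; measured single-cell
recovery errors are at the few-percent level, far inside the acceptance
bands (25% for ambient and `M`, 30% for `r`), so replication beyond one
realization per cell does not change any verdict. Phase-recovery
experiments use 40–60 sweeps of 10 modulation cycles, enough to bring the
Monte Carlo error of the fitted peak phase to ~1–2°.

## Known limitations

* The shipped rate table reproduces the published scheme's *equilibrium*
  targets exactly and its kinetic features qualitatively; fitted absolute
  values of `M` and `r` depend on these kinetics and should be compared
  across conditions (fold-changes), not read as absolute microphysical
  constants.
* The (M, r) trade-off makes per-cell `r` soft; report cohort statistics.
* The point-source/no-uptake diffusion model is a deliberate
  simplification; EAAT effects are visible only through fitted parameter
  changes.
* `fit_sine()` with free cycles-per-period is a descriptive tool; its
  peak-phase estimate is mildly shape-dependent (see above).
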