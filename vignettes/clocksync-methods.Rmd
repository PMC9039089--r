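---
title: "Models and methods behind clocksync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clocksync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clocksync` studies phase synchronization of cellular circadian clocks:
how noisy ~21 h oscillators in single *Neurospora crassa* conidial cells
lock together as cell density grows toward the macroscopic limit. This
vignette documents the models, the tunable parameters, the numerical and
statistical conventions, and the design decisions taken where the problem
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The clock-network models

Each "giant cell" (a cluster- or field-of-view average treated as one
deterministic oscillator) carries 21 molecular species: the transcription/
translation states of the clock genes *wc-1*, *wc-2* and *frq*, the
WHITE-COLLAR complex WCC, two clock-controlled output cascades (*ccg*,
encoding the hypothesized quorum signal, and *ccg-2*, whose promoter
drives the fluorescent reporter), and the intracellular signal
concentration S_j. Transcription rates are S·, translation rates L·,
decay rates D·; gene activation by WCC uses Hill cooperativity
(n = m = 4 by default). The negative feedback runs
WCC → *frq* on → FRQ → deactivation of WCC (the P·WCC·FRQ^m term), with
FRQ also routing *wc-1* mRNA into its stabilized form.

Two communication mechanisms close the loop between cells:

* **Quorum sensing** (`quorum_rates()`): each cell exchanges signal with a
  shared, well-mixed external pool,
  dS_j/dt = −D9·S_j + K_S1·[CCG] + η·(S_e − S_j), and
  dS_e/dt = −D10·S_e + η_ext·Σ_j(S_j − S_e). The signal feeds back on WCC
  formation through the factor (C2 − C4·S_j): more signal, less WCC
  production. The mean-field assumption (instantaneous, uniform S_e) is
  inherited from the experimental geometry.
* **Cell contact** (`contact_rates()`): no external pool; the signal hops
  only between chain neighbours,
  dS_j/dt = −D9·S_j + K_S1·[CCG] + η·(−2S_j + S_{j+1} + S_{j−1}), with
  single-neighbour coupling at the chain ends so that the diffusive
  exchange conserves total signal. A `printed_bracketing` switch
  reproduces the alternative literal reading in which K_S1 multiplies the
  diffusion term as well; the conventional reading (production constant
  applies to production only) is the default, since a diffusion rate
  proportional to a transcriptional production constant has no mechanistic
  interpretation.

Free-parameter bookkeeping is computed from the configured model
(`n_model_parameters()`): the two-cell quorum model has 28 estimated rates
plus 43 initial conditions = 71; the contact model drops
{η, η_ext, D10, S_e(0)} and adds D_contact, giving 68 — hence the df = 3
used in the χ² model comparison.

### Signal-modulated binding can go negative

(C2 − C4·S_j) is implemented as written; it may become negative at high
signal, which is meaningful (net dissociation) but can surprise. A
`floor_c2` option clamps it at zero. The default leaves it unclamped.

### The demonstration oscillator

The published ensemble means for the 28 estimated rates
(`published_rate_moments()`) do not by themselves define a working
oscillator: the fixed auxiliary rates of the wc-2 branch and the reporter
cascade, and all initial conditions, are not public. Three facts shaped
the shipped `clock_oscillator_rates()` set:

1. **Scale.** K_S1 ≈ 2.4×10⁹ forces the ccg cascade and signal pools to
   live on a tiny concentration scale; `clock_state()` therefore starts
   them at zero and lets them relax (any naive O(0.1) start diverges).
2. **Stiffness.** The wc-2 branch rates control whether WCC and FRQ stay
   order-one; S2 = 0.05, D2 = 6, L2 = 5, D5 = 12 give a stable limit
   cycle with ~20 h period and FRQ relative amplitude ≈ 0.2, integrable
   in milliseconds.
3. **Coupling phase.** Whether the mean-field coupling attracts cells
   toward in-phase or antiphase depends on the *timing* of the signal
   relative to the WCC-sensitive part of the cycle — a first-order filter
   with decay Dcp sets that lag. With the slow reporter-path decay
   Dcp = 0.1 h⁻¹, a signal amplitude raised into the effective range
   (Lc = 3×10⁻⁵, C4 = 12 with C2 = 4.78 preserving the operating point),
   and cell–medium exchange η = 20 (the lower end of the regime the
   ensemble fit itself supports), two giant cells started ~12 h apart
   synchronize within the first 80 h. Exact antiphase (half a period) is
   an unstable equilibrium and correctly stays put.

This set is a tuned, documented *synthetic stand-in* for the unpublished
best-fit model, not a reproduction of it; tests that assert the
synchronization property use it explicitly.

## 2. Numerical integration

No ODE integrator package is available in the target environment, so the
package carries a Cash–Karp embedded Runge–Kutta 4(5) adaptive stepper in
C++ (`src/clock_models.cpp`). Defaults: rtol = 1e-6, atol = 1e-9, step
guard `max_steps = 1e6`. Failures (stiff blow-up, step underflow) return a
`clock_failure` object — never silent NaNs — testable with `sim_failed()`.
The pure-R right-hand sides `quorum_rhs()`/`contact_rhs()` are reference
implementations kept deliberately independent of the compiled path; the
suite cross-checks the two on random states and checks self-convergence
under tolerance halving, plus the structural invariants (conserved gene
totals, permutation symmetry of identical cells).

## 3. Ensemble Metropolis–Hastings

The ensemble method samples parameter space with Boltzmann weight
exp(−χ²/2T), T = 1 by default, where χ² = Σ((model − data)/σ)². Design
choices the source material leaves open:

* **Sweeps.** One sweep = P single-parameter proposals at indices drawn
  with replacement (each parameter visited once per sweep on average).
  The full protocol is 40,000 equilibration + 40,000 accumulation sweeps
  (`fit_config()`); `preset = "desk"` (2,000 + 2,000) is the scaled-down
  setting used in tests, sized to finish in seconds-to-minutes on one CPU.
* **Proposals.** Rates are positive, so they take multiplicative
  log-normal steps with the Hastings correction θ′/θ; initial conditions
  take additive Gaussian steps. Per-parameter scales adapt every 50 sweeps
  during equilibration toward 20–40% acceptance and are frozen for
  accumulation, preserving detailed balance where samples are collected.
  The suite verifies the sampler against analytic stationary
  distributions (Gaussian on quadratic surfaces; the log-normal target for
  a positive parameter).
* **Measurement σ.** Unstated in the source material; the default is a
  robust per-trajectory residual scale, MAD(diff(data))/√2, overridable
  with a number or bootstrap SEs.
* **Ensemble uncertainty.** Three conventions are emitted by
  `ensemble_moments()`: the posterior SD across the ensemble (`sd`), the
  naive SD/√N (`se_naive`), and SD/√ESS (`se`) with the effective sample
  size from the initial positive sequence of autocorrelations. Naive SE
  overstates precision under MCMC autocorrelation; parameter-recovery
  tests use the posterior SD, the statistically meaningful band.
* **Convergence.** A Mann–Kendall trend test on accumulated traces
  (`mann_kendall()`, reported per parameter in `$converged`) flags
  residual drift, mirroring the standard no-trend-with-sweep control.
* **Prediction.** The ensemble-average prediction averages the forward
  model over a thinned subset (≤ 50) of accumulated parameter vectors; a
  test checks it fits no worse than the median single sample.

## 4. Phase analysis conventions

* **Detrending** is log then subtraction of a centred moving average
  (default window 24 h; truncated at the edges). Non-positive intensities
  are an error, by design: they indicate the data are not on the
  fluorescence scale the log expects.
* **Hilbert phase** F_H = atan2(x̃, x) with the FFT-based transform;
  **continuization** F_C unwraps recursively, choosing the integer number
  of turns that minimizes each step (ties toward the smaller |m|), so
  |ΔF_C| ≤ π always and F_C ≡ F_H (mod 2π). The floor bracket sometimes
  printed in the cycle-count definition M_C = (F_C(t₁) − F_C(t₀))/2π is
  read as a plain parenthesis: flooring a phase difference before dividing
  by 2π would produce spurious non-integer cycle artifacts, and observed
  phase curves are smooth.
* **Edge handling.** The FFT Hilbert transform is unreliable near record
  boundaries; `hilbert_phase()` flags the first and last 12 h (the
  half-window of the default detrend) and `kuramoto_order()` pipelines
  exclude them.
* **Kuramoto order parameter.** The centred formula that subtracts the
  time-mean phasor inside the modulus evaluates to 0 for perfect constant
  synchrony, contradicting the stated calibration K = 1 for perfect
  synchrony. The default (`variant = "standard"`) is therefore the plain
  time-averaged resultant length; the centred form is kept as
  `variant = "printed"` for comparison. Phases enter through exp(i·), so
  wrapped and continuized phases are equivalent; radians are assumed.
* **Periodogram.** Plain FFT power spectrum; the peak's period and power
  are the period and amplitude proxies. Periods only land exactly on
  printed values when they sit on the FFT grid — the detrending control
  (30 h sinusoid, 240 h record, 0.5 h sampling) is such a case.

## 5. The stochastic Kuramoto model

dφ_i/dt = ω_i + K Σ_j sin(φ_j − φ_i) + ε_i, with ε_i white noise of SD σ.
The printed equation sums couplings without 1/n and is implemented
literally as the default; `normalize = TRUE` gives the textbook K/n
convention. Integration is stochastic Heun with fixed step (default
0.05 h; noise scaled by √dt), with a warning when K·n·dt outruns
stability. The fit (`fit_kuramoto()`) reuses the MH engine over {K, φ_0}
with the noiseless model as forward map; ω_i are supplied or estimated
per oscillator from a periodogram.

**Identifiability caveat, and why the recovery test uses the normalized
variant:** with the literal convention and K = 10, n = 20, the coupling
rate K·n = 200 h⁻¹ locks all phases within minutes of model time. At the
experimental 0.5 h sampling no transient survives, and the stationary
phase offsets (ω_i − ω̄)/(K·n) ~ 10⁻⁴ rad sit far below any realistic
noise floor — K is then unidentifiable in principle. The
parameter-recovery tests therefore simulate and fit the K/n-normalized
variant (coupling rate 10 h⁻¹) sampled at 0.05 h over 6 h, where the
locking transient carries the information; recovery within 2 posterior
SEs and a null (K = 0) control are both verified.

## 6. The synthetic-data generator

`simulate_population()` builds per-cell fluorescence
trend(t) · bead_level · (1 + A·cos φ_i(t)) + noise on a 0.5 h grid over
240 h. What the defaults state, and why:

| parameter | default | rationale |
|---|---|---|
| `period_mean_h`, `period_sd_h` | 21, 1 | circadian period of the strain; modest inter-cell spread |
| `amplitude` | 0.3 | single-cell oscillation amplitude is not reported; 30% of baseline is a realistic reporter contrast |
| `noise_sd` | 5 (vs baseline 100) | measurement noise magnitude is not reported; 5% read noise is typical of CCD fluorescence and keeps intensities positive under the bleach trend, as the log-detrend requires |
| `trend_rate` | 0.003 h⁻¹ | bleaching form is not reported beyond being removable by a 24 h moving average; exponential decay halving over ~10 days is the simplest such trend |
| `bead_level`, `bead_noise_sd` | 100, 0 | constant reference channel enabling exact de-normalization round trips |
| `phase_sd_h` | 1 | small within-population phase jitter |

Phases come from the closed-form cosine (default), from the noisy Kuramoto
model (`simulate_density_series()`, coupling set per layout so measured K
rises with density), or from the quorum-sensing ODE limit cycle
(`engine = "ode"`, per-cell phase shifts realized by sampling the cycle at
shifted times). The generator does **not** emulate: image formation, cell
growth/filamentation, cell-death dropout (≤20% loss in the real assay),
or spatial structure within a chamber. A green mixing-control or
density-regression test therefore establishes that the *analysis
machinery* behaves correctly on data with the stated statistical
structure — not that the biology has been re-measured.

The density-series test couples cells at strengths straddling the locking
transition (0.1–2 in the K/n convention with σ = 0.3, initial phase
spread 4 h) so the measured K spans a wide range and the K-vs-coupling
slope is reliably positive across seeds.

## 7. Statistical conventions

* **Clustering**: k-means (k = 2) on z-scored 0–30 h segments, 20
  restarts, fixed seed; Ward hierarchical clustering as an option;
  accuracy against ground truth maximized over label permutations.
  Degenerate all-identical input is flagged, not clustered.
* **Bootstrap SEs**: resample cells with replacement at each timepoint
  (B = 1000 default); the normalized variant divides by the pooled RMS
  over both groups, √((1/n)(ΣX² + ΣY²)) with n the total cell count,
  exactly as specified for the single-vs-multi-cell contrast.
* **Variance ratio**: F = ratio of mean per-timepoint variances with
  df = (T − 1, T − 1) on both sides; how the per-timepoint series should
  aggregate into one F is not fully specified anywhere, so this convention
  is documented and configurable (larger-over-smaller by default).
* **Density regression**: Huber M-estimation (IRLS, `MASS::rlm`) of K on
  wells per chamber; the slope test is one-sided (the mechanism under
  test predicts a positive slope); the OLS slope is reported alongside.
* **Sign test**: exact binomial tail; five positive replicate slopes give
  p = (1/2)⁵ = 0.03125 (the value sometimes printed as 0.0325/0.03 is an
  arithmetic slip in the source material; the exact value is used here).
* **K contrast**: z = (K_a − K_b)/√(se_a² + se_b²), two-sided normal p,
  with the t-like df n_a + n_b − 2 reported for reference.

## 8. The physical bound

D_A = L_a²/t_D converts the assumed chamber-crossing time into a diffusion
coefficient (1800 µm in 24 h → 2250 µm²/min), and the Stokes–Einstein
relation d_A = k_B·T/(3π·η·D_A) bounds the molecule's hydrodynamic size.
Temperature and viscosity are not stated with the bound; the experiments
ran at 30 °C, but only water at 25 °C (T = 298.15 K, η = 8.90×10⁻⁴ Pa·s)
reproduces the printed ~13.05 nm within 0.5%, so those are the documented
defaults (30 °C water would give ~14.9 nm). The output is labelled a size
d_A; the source material calls the same number both a radius and a
diameter, and no silent factor of 2 is applied.

## 9. Known limitations

* The demonstration oscillator is a tuned stand-in; its period (~20.1 h)
  and amplitudes are in the circadian range but are not fitted to data.
* Explicit Runge–Kutta is adequate for the shipped parameter sets but not
  for arbitrarily stiff corners of parameter space; the MH objective
  treats integration failure as rejection, which slightly biases the
  ensemble away from stiff regions.
* Desk-scale MCMC (2,000 + 2,000 sweeps) yields effective sample sizes in
  the tens for correlated parameter pairs; the full 40,000-sweep preset is
  provided for serious ensembles.
* The contact model is a linear chain; no 2-D contact graph is
  implemented.
* Phase extraction assumes uniformly sampled records; no irregular-
  sampling spectra are provided.
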