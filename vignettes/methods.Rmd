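---
title: "Models and methods behind anestherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anestherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anestherm)
```

# The scientific problem

Core body temperature (T~core~) is a strong modulator of volatile-anesthetic
depth in rodents. Mice anesthetized with isoflurane lose thermoregulation and
their T~core~ drifts toward an equilibrium set by the chamber's ambient
temperature (T~a~) and the dose; in turn the depressed T~core~ deepens the
anesthetic state, which shows up in three read-outs:

* **Emergence latency.** Time from isoflurane cessation to the recovery of
  the righting reflex (RORR) grows steeply as T~core~ at cessation falls, and
  is well described by a one-phase exponential decay in temperature with a
  distinct inflection near 31.9 °C below which every further degree of cooling
  costs hundreds of seconds of emergence time.
* **EEG slowing and burst suppression.** Relative δ-band power (1–4 Hz)
  rises, and the EEG alternates between bursts and near-isoelectric
  suppression epochs; the burst-suppression ratio (BSR, suppressed time over
  total time) falls roughly linearly with mean T~core~.
* **Population activity in thermoregulatory nuclei**, measured by fiber
  photometry, transiently rises around loss (LORR) and recovery (RORR) of the
  righting reflex.

`anestherm` packages the analysis chain for this kind of experiment: a
synthetic cohort generator with known ground truth, the EEG and photometry
signal statistics, the three regression models, and the between-group model
comparisons. Because raw recordings from such studies are typically available
only on request, the generator is a first-class, tested component: it is how
the pipeline is validated end-to-end without any download.

# The generative models

## Core temperature

T~core~ follows first-order (Newtonian) relaxation toward a state-dependent
equilibrium,

$$\frac{dT}{dt} = -r\,\bigl(T - T_{eq}(t)\bigr),$$

with rate $r = 0.15\ \mathrm{min^{-1}}$ by default — fast enough to approach
equilibrium over a ~30-min exposure, which matches the shape of published
cooling curves. Before isoflurane onset the animal thermoregulates, so
$T_{eq}$ is its baseline (drawn per animal, 36.8 ± 0.3 °C); during anesthesia
$T_{eq}$ is the anesthetic equilibrium; after cessation $T_{eq}$ returns to
baseline. Chemogenetic/optogenetic interventions are represented purely as a
±2 °C shift of $T_{eq}$ during their window — the package deliberately does
not model the underlying circuitry.

Two details matter:

* **Anchoring.** For the twelve packaged T~a~ × dose cells the anesthetic
  equilibrium is chosen so that the *noise-free* trajectory hits
  baseline + ΔT₃₂ exactly at cessation, where ΔT₃₂ is that cell's published
  group-mean temperature change (e.g. −4.51 °C for 20 °C/1.4%, +1.70 °C for
  36 °C/0.8%). The published linear T~a~→T~core~ endpoint relation
  (slope 0.66, intercept 14.79) is then a *fitting target* on generated data
  and the fallback equilibrium map for unlisted conditions, not a generative
  constraint — the printed group means and the printed regression line are
  not perfectly consistent with each other, and the group means win.
* **Integration.** Because $T_{eq}$ is piecewise constant, the exact step
  update $T_{n+1} = T_{eq} + (T_n - T_{eq})e^{-r\Delta t}$ is used instead of
  an Euler step; the noise-free 2-min-cadence trace therefore matches the
  closed-form exponential to machine precision, which the tests assert at
  1 × 10⁻⁶ °C.

## Emergence latency

RORR latency is generated from the one-phase decay

$$y = A e^{-kT} + C, \qquad A = 20.3\times10^{5}\ \mathrm{s},\;
k = 0.27\ \mathrm{^{\circ}C^{-1}},\; C = -69.06\ \mathrm{s},$$

evaluated at the animal's T~core~ at cessation, plus Gaussian noise and a
1-s floor. Published per-group latency dispersions scale roughly with the
mean, so the noise standard deviation is `rorr_noise_sd` (absolute seconds,
default 0) plus `rorr_noise_cv` × curve value (default 0.15) — a
coefficient-of-variation term added to the absolute field so that cold
(slow-emerging) and warm (fast-emerging) groups are both realistic.

For cells of the packaged condition table, the generator does **not** read
the cessation temperature off the simulated trace; it inverts the decay curve
at the cell's published group-mean latency
($T = \ln(A/(\bar y - C))/k$, ≈ 27.7 °C for the 20 °C/1.4% group). This
calibration makes the generated latencies reproduce the published group
means by construction and sidesteps the same group-mean/curve inconsistency
noted above. LORR is drawn at 120 ± 20 s independent of temperature, since
induction latency shows no temperature correlation.

## EEG

The EEG generator sums five band-limited Gaussian components (δ 1–4, θ 5–8,
α 9–12, β 13–25, γ 26–60 Hz) with condition-specific variance weights,
synthesized by brick-wall filtering of white noise in the Fourier domain.
The construction puts each component's power exactly inside its band, so the
realized relative band powers match the configured weights to well within
2% absolute (Welch-window smearing at band edges accounts for the
remainder). δ weights come from the published relative powers where printed
(56.66/33.16/27.81% at 20/25/32 °C under 0.8%); the other cells carry values
chosen once on physiological grounds (deeper anesthesia and colder chamber ⇒
more δ), and the remaining weight is split θ:α:β:γ = 32:24:26:18, a
plausible anesthetized-rodent profile.

Burst suppression is an alternating renewal gate multiplied into the signal:
suppression segments are shifted-exponential with mean 1.0 s (minimum
0.5 s); burst-segment means are solved so the suppressed-time fraction
equals a logistic map of the instantaneous T~core~,

$$p(T) = \frac{p_{\max}}{1 + e^{s (T - T_{1/2})}},\qquad
p_{\max}=0.9,\ s=0.2\ \mathrm{^{\circ}C^{-1}},\ T_{1/2}=29\ \mathrm{^{\circ}C},$$

active only while isoflurane is on. A logistic is used because the observed
BSR–T~core~ relation is linear over the measured mid-range while a fraction
must stay in [0, 1]; the default slope at the midpoint
(100·p~max~·s/4 = 4.5%/°C) is in the range of the published BSR-per-degree
slopes (≈3.3–4.4%/°C). Suppressed samples are scaled by 0.05 so suppression
epochs sit far below any sensible detector threshold. The gate is returned
as ground truth, which is what lets the suppression detector be scored
against a known mask.

## Photometry

Raw fluorescence is baseline + slow linear drift + Gaussian noise + one
double-exponential transient per event,
$h(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ with rise 1 s and decay 8 s
(peak at $\tau_r\tau_d/(\tau_d-\tau_r)\,\ln(\tau_d/\tau_r) \approx 2.38$ s
after onset, a closed form the tests use as an oracle), sampled at 50 Hz.

# The analysis chain

**Band powers.** Per epoch (30 s default), a Welch averaged modified
periodogram (4-s Hann segments, 50% overlap → 0.25 Hz resolution, enough for
the 1-Hz lower band edge) is integrated over each closed band interval.
Relative power is band power over the 1–60 Hz total. The band edges are kept
exactly as printed, gaps included, so the five relative powers intentionally
do not sum to 1.

**Suppression detection and BSR.** The literature computes BSR without
stating a detector, so the package declares one: a sample is suppressed when
the 0.1-s moving-RMS envelope stays below threshold for at least 0.5 s. The
default threshold is adaptive — 0.25 × the awake-baseline RMS — which makes
BSR invariant to recording gain; an absolute μV threshold is available. The
centered RMS window blurs each burst/suppression boundary by half a window,
so the detector compensates: the run-length gate is shortened by one window
and detected intervals are re-expanded by half a window per side. On
generated cohorts the detected mask agrees with the ground-truth gate on
>95% of samples. BSR is reported per 1-min bin and overall
(duration-weighted mean of bins); the maintenance window is 0–30 min and the
recovery window runs from cessation (32 min) to RORR.

**Photometry.** ΔF/F = (F − F₀)/F₀ and Z = (F − μ)/σ with F₀, μ, σ from a
50-s baseline window immediately preceding the alignment event (isoflurane
start for LORR analyses, cessation for RORR analyses). Peri-event alignment
uses inclusive endpoints (a (−50, +100) s window at 50 Hz is 7501 samples)
with nearest-sample event placement; trials without full coverage are
dropped with a warning. Peak statistics take an explicit search window —
whether a bounded window was used in the source analyses is not stated, so
it is a required parameter rather than a hidden default — and break ties at
the earliest time. The 410-nm isosbestic channel is not modeled or
corrected: no correction formula is published for this workflow, so the
processing operates on the signal channel.

**Latency extraction.** The cage-flip log (15-s cadence) yields LORR as the
first failed righting after isoflurane start and RORR as the first
successful righting after cessation. Whether a single failure or sustained
failure defines LORR is not specified in the source protocol; first-failure
is the default, with a two-consecutive-failures mode available. Extracted
latencies are therefore the true latency rounded up to the next flip.

**Regression models.**

* `fit_linear()` — ordinary least squares with R², slope p-value.
* `fit_one_phase_decay()` — Levenberg–Marquardt on $y = Ae^{-kx}+C$ with the
  bound k ≥ 0 (emergence latency cannot increase with temperature in this
  model family), multi-started from five plateau candidates below min(y)
  each seeding a log-linear regression; the best SSE wins, and total failure
  returns a flagged (`converged = FALSE`) profile-grid fallback rather than
  a silent wrong answer. The (A, k, C) parameterization maps to the
  spreadsheet (Y0, plateau, K) convention via A = Y0 − plateau.
* `fit_breakpoint()` — the segmented model
  $y = b_1 (x < b_2)(x - b_2) + b_3$ fitted by profiling b₂ on a 0.01 °C
  grid (candidates need ≥2 points on each side), conditional linear least
  squares for (b₁, b₃), smallest b₂ among SSE ties, then a local continuous
  polish. Flat profiles are flagged unidentifiable with b₃ = mean(y).
* `compare_linear_fits()` — extra-sum-of-squares F tests of parallelism then
  elevation. `compare_decay_rates()` — shared-k (5-parameter) vs separate-k
  (6-parameter) joint fits; both SSEs are computed by profiling k with the
  conditional (A, C) solved linearly, which guarantees the nested SSE
  inequality. All tests use F distributions with (Δparams, n − params)
  degrees of freedom; least squares is unweighted throughout, as in the
  source analyses.

**Group statistics.** `compare_groups()` provides pooled-variance unpaired
and paired t tests with mean ± SEM and a Bonferroni family factor.
Repeated-measures ANOVA reproduction is out of scope; per-band comparisons
with a family of 5 are the documented simplification.

# Problem sizes, tolerances, and what the tests show

The validation suite runs entirely on generated data at deliberately modest
sizes chosen as realistic for this design: cohorts of n = 7 per condition
(the published design), 12 conditions for parameter-recovery work (n = 84),
30-minute 500-Hz EEG for spectral calibration, 200 replicates for power and
calibration studies. Key numerical checks:

* exact recovery (machine precision) of the linear model from noise-free
  points; k and C of the decay model to 3 significant figures from 40
  noise-free points; b₂ to ±0.02 °C and b₁ to ±0.5 from noise-free
  segmented data at 0.5 °C spacing;
* grid-search SSE oracles bounding both nonlinear fitters from above;
* mean δ relative power of the 20 °C/0.8% profile within 2 percentage
  points of the published 56.66%;
* grand-mean simulated RORR for 20 °C/1.4% within 5% of the published
  1074.29 s over 200 cohorts of 7;
* median |k̂ − 0.27| < 0.03 under 10%-of-range noise at n = 84.

Passing these shows the pipeline is internally consistent and recovers the
models it assumes from data that *obey* those models at realistic noise.
It does not show that real recordings obey them: the generator produces
stationary band-limited Gaussian EEG (no artifacts, no line noise, no
non-stationarity beyond the gate), photometry without bleaching or
hemodynamic contamination, and temperature dynamics without circadian or
handling effects. The optional 50-Hz notch and low-pass flags exist for real
data but default off because synthetic data needs neither.

# Known limitations

* EDF reading is not implemented; EEG I/O is CSV (`time_s,uv`).
* No isosbestic correction, spike inference, or motion correction.
* No mixed-effects or Bayesian latency models; no bootstrap intervals.
* The exact sampling rate and suppression threshold used by reference
  analyses are unpublished; the defaults here (500 Hz, 0.25 × awake RMS)
  are declared choices, not inferences.
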