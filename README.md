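# anestherm

Analysis of the interaction between core body temperature and volatile
anesthesia depth in rodents. Cooling deepens isoflurane anesthesia: core
temperature (T<sub>core</sub>) drifts toward an ambient- and dose-dependent
equilibrium during exposure, and the depressed T<sub>core</sub> at cessation
controls how long the animal takes to regain its righting reflex (RORR),
how much δ-band (1–4 Hz) power the EEG carries, and how much of the record
is spent in burst suppression. `anestherm` is for experimenters and analysts
who collect this kind of data — temperature logs, EEG, fiber photometry,
cage-flip righting tests — and want the standard read-outs and regression
models in one tested pipeline.

## What it computes

**Models** (the package's core):

- Linear regression of T<sub>core</sub> at cessation on ambient temperature
  T<sub>a</sub>: `Y = slope·X + intercept` (`fit_linear`).
- One-phase decay of emergence latency on T<sub>core</sub> at cessation:
  `y = A·e^(−k·T) + C`, Levenberg–Marquardt with multi-start and the bound
  k ≥ 0 (`fit_one_phase_decay`).
- Segmented (breakpoint) latency model
  `y = b1·(x < b2)·(x − b2) + b3`, fitted by profiling the breakpoint b2 on
  a 0.01 °C grid with conditional least squares (`fit_breakpoint`).
- Extra-sum-of-squares F tests comparing two groups' lines (slopes, then
  intercepts) and two groups' decay rates (`compare_linear_fits`,
  `compare_decay_rates`).

**Signal statistics**: relative band powers δ/θ/α/β/γ over a 1–60 Hz total
(Welch averaged periodogram, 4-s Hann segments), burst-suppression ratio
from a moving-RMS suppression detector with an adaptive gain-invariant
threshold, ΔF/F and baseline Z-scores for photometry with peri-event
alignment and peak statistics, and LORR/RORR extraction from 15-s cage-flip
logs.

**Synthetic cohorts**: a seeded generator producing temperature traces
(first-order relaxation anchored to published group endpoints),
burst-suppression EEG with a ground-truth gate, event-locked photometry
transients, and righting logs whose latencies follow the decay model above
— so the whole pipeline is testable with known truth and no data download.

## Worked example

Simulate a cold-chamber vs warm-chamber contrast at 1.4% isoflurane
(n = 7 per group), summarize, and compare emergence latencies:

```r
library(anestherm)
cfg <- cohort_config(
  conditions = list(condition(20, 1.4, group_label = "cold"),
                    condition(32, 1.4, group_label = "warm")),
  n_per_group = 7, seed = 42)
co <- generate_cohort(cfg, modalities = c("temperature", "righting"))
s <- summarize_cohort(co)
aggregate(cbind(t_core_32, rorr_s) ~ group, s, mean)
#>   group t_core_32     rorr_s
#> 1  cold  32.30410 1005.00000
#> 2  warm  35.51173   53.57143
compare_groups(s, "rorr_s")
#> rorr_s [unpaired t (pooled variance)]: cold 1005 +/- 56.6 (n=7) vs warm 53.57 +/- 3.03 (n=7)
#>   t(12) = 16.79, p = 1.067e-09, Bonferroni-adjusted p = 1.067e-09
```

Cold-chamber animals end anesthesia ~3.2 °C cooler and take ~19× longer to
right themselves — the temperature–emergence coupling the decay model
formalizes. The model fitters recover their generating parameters exactly
from noise-free data:

```r
x <- seq(26, 36, by = 0.5)
y <- -307.47 * (x < 31.88) * (x - 31.88) + 60.48
fit_breakpoint(x, y)
#> Breakpoint fit: b1 = -307.5, b2 = 31.88, b3 = 60.48  (R2 = 1.000, n = 21)
```

Here `b2` is the inflection temperature: above ~31.9 °C extra warmth barely
changes emergence time (plateau `b3` ≈ 60 s), below it each lost degree adds
|b1| ≈ 307 s. A full demo pipeline (EEG + photometry included) runs with:

```r
run_pipeline(system.file("extdata/demo_cohort.yaml", package = "anestherm"),
             out_dir = "demo_out")
```

A command-line wrapper with `simulate` / `analyze-eeg` /
`analyze-photometry` / `fit-models` / `report` / `run` subcommands is
installed at `system.file("cli/anestherm.R", package = "anestherm")`.

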