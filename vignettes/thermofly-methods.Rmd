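---
title: "Models and methods behind thermofly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermofly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofly)
```

## What the package models

Warming *Drosophila* from its preferred ~25 °C to 31 °C roughly doubles
open-field locomotor activity.  The behavioral phenotype is described by a
small set of metrics extracted from position tracks sampled every 0.2 s in
35-mm circular arenas over 60 min: the percentage of time active, mean
walking speed, the action-initiation rate, walking-bout and
inter-bout-interval (IBI) durations, the Weibull shape factor κ of the IBI
distribution, and the walking-speed change after a mechanical startle
stimulus delivered at 30 min.  The neuronal side of the assay is quantified
from GCaMP ΔF/F₀ ramp responses, CaMPARI red/green photoconversion ratios,
and whole-cell current-clamp recordings.

Because raw tracking data for this kind of assay are rarely deposited, the
package pairs every analysis stage with a seeded synthetic-data generator
with known ground truth.  The generator's defaults are the published
per-condition parameter sets (`preset_config()`), so the analysis pipeline
can be validated end to end as a parameter-recovery exercise.

## The locomotor model

A fly is modeled as a two-state alternating renewal process:

* **walk bouts** with durations from an exponential law (mean
  `bout_mean_s`; a gamma option is provided).  The exponential family is a
  modeling choice — the behavioral literature reports only the mean bout
  length — and nothing downstream depends on it beyond the mean.
* **pauses** (IBIs) with durations from a Weibull law with shape
  `pause_shape_k` (κ) and mean `pause_mean_s`.  κ < 1 produces the bursty,
  heavy-tailed pausing characteristic of real flies; κ = 1 is memoryless.

During a bout the fly advances at a per-bout speed drawn from
N(`speed_mean_mm_s`, `speed_sd_mm_s`) (truncated at 1.2 mm/s so walking
remains distinguishable from jitter) along a persistent-random-walk heading
with wrapped-Gaussian turning (σ = 30°/step) and specular reflection at the
arena wall.  The heading model is cosmetic: no reported metric depends on
it, only on displacement magnitudes.  During a pause the position jitters
within 0.045 mm of an anchor point, i.e. < 0.1 mm displacement per step —
real tracking is never perfectly still, and this makes the activity
threshold a meaningful, testable parameter.

### Resolution of durations on the sampling grid

A track sampled every `sample_dt_s` = 0.2 s cannot represent a pause
shorter than one sample.  This matters enormously for heavy-tailed pause
laws: a continuous Weibull with κ = 0.45 and mean 0.9 s has its *median*
at 0.16 s, below one sample.  If the generator produced continuous
durations, most pauses would be invisible to any analysis at this
resolution, and the observable statistics would not match the configured
ones no matter how good the analysis is.

The generator therefore draws continuous durations and rounds them to the
nearest grid multiple (minimum one sample), and calibrates the continuous
scale parameter numerically (by root finding on the exact discretized
mean) so that the *generated, grid-resolved* durations have exactly the
configured mean.  Two consequences:

* the renewal identity — fraction of time active equals
  `bout_mean / (bout_mean + pause_mean)` — holds exactly in expectation
  for the generated ground truth, and
* the analysis pipeline can recover the configured means without a
  resolution-induced bias.

The configured κ remains the shape of the underlying continuous law;
discretization biases a shape factor *fitted to the generated data*
slightly downward (by roughly 5–10 % for the study's κ range), which is
why the pipeline-level κ check is looser than the continuous-sample one.

### Equilibrium start

Recordings open on ongoing behavior (flies acclimatize in the arena for an
hour before tracking starts).  The generator therefore starts each session
in the *equilibrium* state of the renewal process: the initial state is
chosen by stationary occupancy and the first interval is a residual-length
draw with P(r) ∝ P(L ≥ r).  Starting with an ordinary draw instead would
under-represent time spent in rare very long pauses across a finite
session — a 2–3 % bias in pause time for κ ≈ 0.27 — which propagates
directly into activity and initiation-rate estimates.

### Startle

The mechanical stimulus (five 200-ms pulses at 800-ms gaps, 4.2-s span) is
followed by a speed shift of `startle_delta_mm_s` applied to walking steps
for `startle_window_s` = 60 s.  The published assay reports a single
post-stimulus speed change without stating a window; 60 s is this
package's choice, mirrored exactly in `startle_response()`.  Both the
generator and the analysis treat the startle as a change in *walking*
speed: `startle_response()` averages speed over active samples by default
(`active_only = FALSE` restores a plain mean over all samples, which
scales the recovered shift by the activity fraction).

## Locomotor analysis choices

* **Activity threshold** 1.0 mm/s instantaneous speed.  The tracking
  software used for the original assay does not state its criterion; 1.0
  mm/s separates the generator's walking speeds (≥ 1.2 mm/s) from pause
  jitter (≤ 0.45 mm/s) with margin on both sides, and is exposed
  everywhere as a parameter.
* **Minimum bout/IBI duration** one sample (0.2 s).  With heavy-tailed
  pause laws at the published means, 55–75 % of pauses last exactly one
  sample; any larger minimum merges them into walking and destroys the
  initiation-rate and IBI statistics.  For noisy real-world tracks the
  minima can be raised (runs shorter than the minimum are reassigned to
  the flanking state, shortest first, walk-priority on ties).
* **Censoring.**  The first and last interval of every session touch the
  recording edges; they are excluded from duration means and initiation
  counts but their time still counts toward occupancy.
* **Initiation rate** is defined per second of *inactive* time — the
  definition uniquely consistent with the published pairs (1/3.2 ≈ 0.3,
  1/0.9 ≈ 1.1 s⁻¹).  Condition-level rates are pooled (total onsets /
  total pause time): per-fly rates are ratios with a heavy-tailed random
  denominator, and averaging them carries a Jensen-type upward bias of
  5–7 % at the 25 °C parameter set.  Per-fly rates are still reported in
  the per-fly table.  Other metrics are averaged per fly, then across
  flies.

## Burstiness: the Weibull shape factor

κ is estimated by least squares on the empirical cumulative IBI
distribution, `F(x) = 1 − exp(−(x/λ)^κ)`, using median-rank plotting
positions `(i − 0.3)/(n + 0.4)` and a linearized-Weibull start
(regression of `log(−log(1−F))` on `log x`), refined by BFGS on
`(log κ, log λ)`.  IBIs are pooled across flies within a condition, as a
single κ per condition is the published convention; censored edge
intervals are excluded because a plain CDF fit cannot absorb censoring.

Tied values — ubiquitous in grid-resolved data — are collapsed to their
highest plotting position, so the fit targets the empirical CDF at each
distinct value.  Fitting every tied point individually places a vertical
cloud of plotting positions at each grid value and drags the fit toward
κ ≈ 1 regardless of the data; this failure mode is easy to reproduce and
is the reason the collapse is not optional.  Maximum-likelihood estimation
(`fit_weibull_mle()`, via fitdistrplus) is provided as a cross-check; on
large continuous samples the two agree within 5 %, while on grid-resolved
data MLE is strongly biased upward by the point mass at one sample and the
CDF fit is the meaningful estimator.  A zero-variance sample has no finite
Weibull shape and is reported capped at 1000 with a `degenerate` flag.

## Calcium imaging

* **ΔF/F₀** uses F₀ = mean of the first five frames, acquired before any
  temperature change; the generator always holds the bath at 20 °C for the
  first frames to honour that convention.  No background subtraction or
  bleaching correction is applied (none is part of the assay).
* **Ramp responses** report the peak (first maximum on ties) and the
  average over the *full* 20→35→20 °C ramp; whether the published
  "average" spans the heating phase only is not stated, and the full ramp
  is this package's choice.  Temperature is aligned to frame times by
  nearest-sample lookup.
* **CaMPARI** photoconversion is the mean red over mean green signal of
  the maximum-intensity projection within a hand-drawn ROI, ×100.  The
  published percentages are read as ratio × 100.  ROIs are supplied masks;
  no automated segmentation is attempted because the original ROIs were
  drawn manually.
* The synthetic movie embeds transients whose peak is attained exactly at
  a frame, so noiseless recovery is exact; with pixel noise σ the ROI-mean
  peak bias stays below 3σ/(F₀√m) for an m-pixel mask.

## Electrophysiology

Spikes are upward crossings of −20 mV with a 2-ms refractory period; a
depolarized plateau (depolarization block) yields a single onset crossing
and no further events.  f–I curves divide within-step spike counts by the
step duration.  Passive properties come from hyperpolarizing steps: RMP is
the pre-step mean, Rin the steady-state deflection (final 20 % of the
step) over the step current.  Bursts are maximal spike groups with
inter-spike intervals below 100 ms.  The synthetic traces use a 30-ms
membrane time constant, a 15-mV cap on sub-threshold depolarization during
spiking steps (spike-generating conductances shunt the membrane; without
the cap, Ohmic depolarization at +40 pA × 1185 MΩ would park the baseline
above the detection threshold), and a stylized 2-ms triangular spike.

### Liquid junction potential

`henderson_ljp()` implements the generalized Henderson equation with
conductivity-consistent weights (mobilities are limiting molar
conductivities per charge squared, relative to K⁺).  Gluconate's relative
mobility is set to 0.33; EGTA and HEPES are treated as negligibly mobile
and glucose is neutral — the original report names only the resulting
13 mV, not a mobility set, so agreement to the millivolt necessarily
depends on these documented conventions.  At 25 °C the printed pipette and
bath compositions give 13.13 mV with this table.  The implementation
reduces exactly to the Lewis–Sargent closed form for a single binary salt
(a useful property check: with the standard table a tenfold KCl dilution
gives 1.13 mV, small but not zero, because u_K and u_Cl differ by ~4 %).
The sign convention is the whole-cell correction convention: the returned
value is subtracted from recorded voltages.

## Statistics

Each group passes a normality gate: D'Agostino–Pearson for n ≥ 8,
Shapiro–Wilk below (the published "small N" cut is qualitative; 8 is the
smallest n for which the kurtosis transformation is defined).  The
parametric branch runs one-way ANOVA with single-step Dunnett comparisons
of both parental controls against the experimental group; the
non-parametric branch runs Kruskal–Wallis with Dunn's rank comparisons
(tie-corrected, Bonferroni over the two control contrasts).  Dunnett was
chosen over Šidák for the parametric branch because the design is
many-to-one; both appear in the original report without a stated mapping.
An effect is significant only if the experimental group differs from
*both* controls — a rule that is never less conservative than either
pairwise test, with empirical type-I error far below α under the global
null.  Two-group designs use Welch's t-test or Mann–Whitney under the same
gate.  No cross-metric correction is applied by default (tests are
reported per metric); a Benjamini–Hochberg option exists on the summary
table.

## What the generator does and does not emulate

The synthetic cohorts emulate the *statistical* structure of the assay:
renewal bout/pause alternation, heavy-tailed IBIs, per-bout speed
variability, a startle speed shift, arena confinement, tracking jitter.
They do not emulate video segmentation artifacts, identity swaps, wall
interactions beyond specular reflection, circadian or thermal adaptation
drift within the hour, or any biophysics of the underlying circuitry.
Passing recovery tests therefore demonstrates that the analysis measures
what it claims to measure at the stated sampling resolution — not that
real tracking data are free of artifacts the generator does not contain.

## Problem sizes and numerical tolerances

The package's own validation uses cohorts of 150 flies × 60 min at 0.2-s
sampling for the locomotor recovery checks (the published cohort is 138
wild-type flies), 10,000-interval samples for estimator checks, noiseless
stacks for imaging exactness (recovered to numerical precision), and 1000
replicates for the type-I simulation.  Scale calibration solves the
discretized-mean equation to 10⁻⁹ s; Weibull fits optimize in log-space
and report the CDF RMSE.  Conditions with unpublished parameters
(`c232-shi31`, `R78B06-shi31`) fall back to the 31 °C wild-type values for
the missing fields, as documented in `?preset_config`.
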