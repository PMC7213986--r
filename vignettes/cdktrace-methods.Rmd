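---
title: "Methods: dual CDK4/6–CDK2 reporter trace analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual CDK4/6-CDK2 reporter trace analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdktrace)
library(dplyr)
```

## The measurement problem

Kinase translocation reporters (KTRs) read kinase activity as the
cytoplasmic:nuclear fluorescence ratio of an engineered substrate. A
CDK4/6-selective KTR imaged together with a CDK2 KTR and an APC/C^Cdh1^
degron reporter gives, per cell and per 12-minute frame, three time series:
the raw CDK4/6 reporter ratio, the CDK2 ratio, and a degron intensity that
starts accumulating when APC/C^Cdh1^ is inactivated at the G1/S transition.

The raw CDK4/6 reporter is not a pure CDK4/6 readout: a fraction of the
signal tracks CDK2 activity, which matters most in S/G2 where CDK2 is high.
`cdktrace` implements the analysis chain for such data: cross-contribution
correction, event detection, fate classification, and population
statistics, plus a synthetic cohort generator that provides ground truth
for every stage.

## The correction model

The corrected CDK4/6 activity is

$$\mathrm{CDK4/6_{corr}} = \mathrm{CDK4/6_{raw}} - f\,\mathrm{CDK2},
\qquad f = 0.35 .$$

`estimate_correction_factor()` recovers $f$ from an acute CDK4/6-inhibition
experiment: with the CDK4/6-specific signal nulled, whatever raw signal
remains in S/G2 cells is the CDK2 contribution, so an ordinary
least-squares fit of raw signal against simultaneous CDK2 activity across
pooled (cell, frame) points estimates $f$ as the slope. Three choices are
deliberate:

* **Free intercept.** Inhibitors leave a nonzero signal floor; forcing the
  regression through the origin would bias the slope.
* **Two-frame burn-in.** CDK substrate dephosphorylation after inhibition
  completes within minutes, so one 12-min frame can be transitional; the
  first two post-addition frames are excluded.
* **S/G2 gating and pooling.** Only cells whose degron was already rising
  before the inhibitor entered the fit (G1 cells reverse their CDK2
  trajectory after CDK4/6 inhibition, violating the static composition).
  Frames are pooled across cells into a single fit rather than fitted per
  cell and averaged; per-cell fits are noisy at a 4 h window and the
  composition model is global.

Negative corrected values are kept; clipping is a display concern and
would distort downstream statistics.

## Event detection

All detection runs on running-median–smoothed series (window 3 samples by
default — a single-frame segmentation glitch is the dominant artifact in
tracked single-cell data, and a 3-point median removes exactly that while
deferring everything else to the persistence rule).

* **CDK4/6-on / CDK2-on** (`detect_onset()`): the first grid time at which
  the (corrected) activity exceeds its threshold — 0.7 for CDK4/6, 0.76
  for CDK2 — and stays above it at every unmasked sample for a persistence
  window (2 h for CDK4/6, matching the post-mitotic classification window;
  1 h for CDK2, whose ramp is slower and whose threshold crossing is
  therefore noisier). Onset times are reported as the first above-threshold
  frame, never interpolated, so results are grid-aligned and reproducible.
  Masked samples are skipped rather than treated as failures.
* **APC/C-off** (`detect_apc_off()`): baseline mean and sd are estimated
  from the flat pre-rise segment (expanding from the start), and the rise
  onset is the first time the degron exceeds baseline + 3 sd with at least
  two follow-up samples above threshold over the next hour and no net
  decrease of the smoothed signal. The two-sample follow-up requirement
  exists because a blip on the final frame of a trace has no evidence of
  being a rise; without it, end-of-trace noise produces false G1/S calls
  in quiescent cells.

## Fate classification

* **Quiescence release** (`classify_cohort(context =
  "quiescence_release")`): *high* iff an onset was detected and corrected
  CDK4/6 stays above threshold through the APC/C-off point or the trace
  end. "Persistently increased" needs a horizon; the trace end is the
  least arbitrary one.
* **Mitotic exit**: *high* iff corrected CDK4/6 exceeds 0.7 at every
  unmasked frame within 2 h after anaphase (using the whole window rather
  than the single 2 h frame, for noise robustness); among the rest,
  *delay* iff a sustained onset occurs later, with the transient-G0
  duration reported; *low* otherwise (below threshold at the 2 h and 10 h
  checks). Cells with under 10 h of post-anaphase recording are flagged
  truncated rather than silently mislabelled. Any post-2 h onset counts as
  delay, including the rare ones after 10 h.
* **Stress outcome**: cells are eligible when, at the moment stress is
  applied (11 h), both kinase activities are above threshold and the
  degron is flat. Eligibility uses the instantaneous smoothed state at
  that time, not post-treatment persistence — selecting on what happens
  after the treatment would bias the dose–response (cells that exit
  immediately would fail a persistence filter precisely because they
  responded). The outcome at 15 h is *low* (exit) iff CDK2 is below 0.76
  **or** has declined more than 20% from its value at stress; the relative
  clause catches cells that reverse clearly while still sitting above the
  absolute threshold. The 20% value is a declared convention.

## Bimodality and mixture thresholds

`bimodal_threshold()` fits a 2-component Gaussian mixture to
log-intensities (Rb phospho-S807/811 immunofluorescence is bimodal on the
log scale) and returns the equal-posterior boundary, falling back to the
kernel-density antimode when the fit degenerates and to the median (with a
warning) when the components are closer than one pooled sd.

`is_bimodal()` decides whether a distribution is bimodal the way one reads
a histogram: a 2-component mixture must be preferred by BIC *and* the
kernel density must show two modes with a genuine dip (valley below 90% of
the lower peak, peaks under 10% of the maximum ignored as tail ripples).
BIC alone is not a bimodality test — at large n it detects any latent
mixture even when the resulting density is strictly unimodal, which is
exactly the situation of CDK2 activity shortly after mitosis:
heterogeneous, but single-peaked.

## The synthetic cohort generator

`simulate_quiescence_release()` and `simulate_cycling()` generate latent
noiseless signals from piecewise-linear kinetic shapes and compose the
observed raw CDK4/6 reporter as
`corrected + f_true * CDK2 + N(0, noise_sd)` per frame, mirroring the
additive cross-contribution of the physical reporter. Defaults are the
study conditions of the experiments the package emulates:

| parameter | default | meaning |
|---|---|---|
| `dt` | 0.2 h | 12-min imaging interval |
| `p_activate` | 0.54 | activating fraction at mitogen release |
| `delay_range` | 5–13 h | delay before rapid CDK4/6 activation |
| `rise_time_cdk46` | 1 h | baseline-to-plateau rise (fast vs the delay) |
| `plateau_cdk46` | 0.9 (sd 0.04) | corrected CDK4/6 plateau |
| `cdk2_baseline` | 0.5 (sd 0.10) | elevated CDK2 baseline |
| `cdk2_slope` | 0.11/h (sd 0.02) | gradual CDK2 ramp |
| `cdk2_lag` | 1 h | CDK4/6-on to CDK2 ramp start |
| `apc_trigger_cdk2` | 1.0 | CDK2 level at G1/S (degron rise) |
| `mitotic_fate_probs` | 0.5/0.2/0.3 | high/low/delay at mitotic exit |
| `delay_fate_range` | 2–9 h | transient G0 duration |
| `noise_sd` | 0.03 | per-frame measurement noise |
| `f_true` | 0.35 | CDK2 contamination fraction |

The CDK2 ramp slope is set so the activity crosses the 0.76 "on" threshold
a couple of hours after its ramp starts and reaches the S-phase level 1.0
roughly two hours later, consistent with observed trace shapes; the
baseline 0.5 reads the post-mitotic "starts elevated" level off the traces
and is configurable. Per-cell heterogeneity (plateau, slope, baseline sds,
with draws truncated so that threshold semantics stay unambiguous —
plateaus in [0.8, 1], CDK2 baselines below the 0.76 threshold) is what
gives population histograms realistic spread; without it every
distribution is a pair of spikes and bimodality analyses are meaningless.
Ground-truth event times are recorded as the grid times at which the
*noiseless* signals cross the analysis thresholds, which is the quantity
the detectors estimate.

Perturbations (`apply_perturbation()`) act on the latent signals and
recompose the observations with fresh seeded noise, so the additive
composition survives the perturbation exactly:

* a CDK4/6 inhibitor nulls the corrected signal within 2 frames, leaving
  `f_true * CDK2` visible in the raw channel (the unsuppressible
  fraction); G1 cells hold CDK2 briefly, then slowly reverse, and no
  longer enter S phase;
* a CDK2 inhibitor collapses CDK2 toward a floor chosen so the raw CDK4/6
  reporter drops by `cdk2_reduction` (default 15%, within the observed
  10–20% range) — stating the effect directly in terms of the quantity
  that was measured while keeping the composition consistent;
* stress draws cell-cycle exit per degron-flat cell from a decreasing
  logistic in CDK2 activity at the stress time (midpoint 0.9, steepness
  10 by default; the data constrain the monotone decrease, not the
  functional form). Exiting cells decay CDK4/6 exponentially (2/h) toward
  baseline first; CDK2 is frozen at its stress-time value for
  `cdk46_to_cdk2_lag` hours (1 h by default, 0 for NaCl-like osmotic
  stress) and then decays at the same rate. Freezing during the lag keeps
  exiting cells from slipping into S phase mid-response and reproduces
  the plateau-then-fall CDK2 shape. Cells already accumulating degron
  never exit.

### What the generator does and does not emulate

It reproduces: sampling rate, delayed-but-rapid CDK4/6 activation, the
gradual CDK2 ramp and its ordering relative to CDK4/6 and APC/C, trimodal
mitotic-exit fates, the additive reporter composition, bimodal corrected
CDK4/6 vs single-peaked CDK2 population histograms shortly after mitosis,
the CDK2-dependent monotone stress response with S-phase resistance, and a
bimodal terminal Rb phospho readout coupled to the CDK4/6 state
(lognormal components at 1 and 10, sd 0.3 on the log scale — the data
constrain bimodality, not the values).

It does not emulate: autocorrelated or multiplicative measurement noise,
segmentation/tracking failures beyond simple masking, lysosomal background
accumulation of the reporter, cell-to-cell coupling, or mechanistic
cyclin D/p21 dynamics. Tests passing on synthetic cohorts therefore
validate the *analysis chain* under the stated kinetic assumptions, not
the biology of any particular cell line.

## Numerical and protocol choices

* Missing frames are masked (`NA`), never interpolated; every detector and
  classifier skips masked samples. Smoothing preserves masks.
* Running medians shrink their window symmetrically at trace edges, so
  series length never changes and `window = 1` is the identity.
* Cumulative activation curves use all tracked cells as the denominator
  (right-censoring); cells without the event never contribute to the
  numerator.
* Bootstrap intervals resample whole cells, not frames — frames within a
  cell are strongly dependent.
* Stress dose–response bins default to width 0.1 from the CDK2-on
  threshold (0.76) to 1.2 with an open top bin, spanning the G1 range up
  to the S-phase level; bins with under 5 cells are flagged.
* Problem sizes used in the shipped analyses: correction-factor recovery
  on ~260-cell inhibited cohorts (≥200 in S/G2), release classification
  on 1000 cells, bimodality and stress dose–response on 1500–4000 cells,
  live-fixed matching on 3000 cells — large enough that binomial error is
  well inside the tolerances being checked, and small enough to run
  comfortably on a laptop.
* The live-fixed comparison (cumulative CDK4/6-on fraction versus Rb
  phospho-positive fraction by time since anaphase) simulates a 15 h
  recording with anaphases spread over 1–13 h, so the fixation time
  samples the rising part of the activation curve; the comparison
  restricts each time bin's cumulative estimate to cells observed at
  least that long after anaphase, since a cell fixed 3 h after mitosis
  carries no information about 9 h onsets.

## A worked example

```{r example}
params <- generator_params(n_cells = 200, seed = 1)
cohort <- simulate_quiescence_release(params)
events <- detect_events(cohort)
fates <- classify_cohort(cohort, events, context = "quiescence_release")
table(fates$label)

curve46 <- cumulative_fraction(events, "t_cdk46_on",
                               seq(0, 24, by = 0.5))
head(as.data.frame(curve46), 3)
```

```{r example-correction}
inhibited <- apply_perturbation(
  simulate_quiescence_release(
    generator_params(n_cells = 260, p_activate = 1, noise_sd = 0.02,
                     seed = 1)),
  perturbation_spec("cdk46_inhibitor", t_add = 20))
fit <- estimate_correction_factor(inhibited, window = 4)
glance(fit)
```

## Known limitations

* One global contamination fraction; no per-cell random effects.
* Onset persistence rules are declared conventions validated by
  ground-truth recovery, not derived from the data.
* The stress model's logistic parameters and decay rates are free choices
  constrained only by monotonicity and kinetic ordering.
* The CDK2-channel three-way mitotic classification is not an independent
  pipeline; it is the same operations run on the CDK2 channel with its
  threshold.
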