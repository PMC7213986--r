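# cdktrace

Analysis of simultaneous CDK4/6 and CDK2 kinase-translocation-reporter
(KTR) traces from live-cell imaging.

Single cells expressing a CDK4/6 KTR, a CDK2 KTR and an APC/C^Cdh1^
degron reporter yield, per cell and per 12-min frame, two
cytoplasmic:nuclear activity ratios and a degron intensity marking S-phase
entry. The raw CDK4/6 reporter carries an additive CDK2 cross-contribution
that dominates its residual signal in S/G2, so the quantity analysed
throughout is the corrected activity

    CDK4/6_corr = CDK4/6_raw − f · CDK2,   f = 0.35,

with *f* estimable from acute CDK4/6-inhibition experiments by regressing
the post-inhibition raw signal on simultaneous CDK2 activity across pooled
S/G2 frames. On top of the correction the package provides:

* threshold-with-persistence detection of the CDK4/6-on (corrected
  activity > 0.7), CDK2-on (> 0.76) and APC/C-off (degron rise) points per
  cell;
* fate classification at quiescence release (high/low), mitotic exit
  (high/low/delay, scored 2 h and 10 h after anaphase) and after acute
  stress (CDK2^inc vs CDK2^low at 15 h);
* population statistics: event-aligned activity matrices, cumulative
  activation curves, bootstrap median bands, stress exit fractions binned
  by CDK2 activity at the time of stress, phase-plane trajectories, and
  live-fixed matching of CDK4/6 state against bimodal Rb phospho-S807/811
  intensities;
* a seeded synthetic cohort generator
  (`simulate_quiescence_release()`, `simulate_cycling()`,
  `apply_perturbation()`) that emulates the kinetic structure of the
  imaging data — delayed rapid CDK4/6 activation, gradual CDK2 ramps,
  degron accumulation at G1/S, trimodal mitotic-exit fates,
  inhibitor and stress responses — and carries ground-truth event times
  and labels for every cell, so the whole analysis chain is testable
  end to end.

Everything is tidyverse-shaped: track tables are long tibbles (one row per
cell per frame), every analysis returns a tibble, fitted objects support
`tidy()`/`glance()`, and result types have `autoplot()`/`plot_*()`
helpers.

## A worked example

```r
library(cdktrace)

cohort <- simulate_quiescence_release(generator_params(n_cells = 200, seed = 1))
events <- detect_events(cohort)
fates  <- classify_cohort(cohort, events, context = "quiescence_release")
table(fates$label)
#>
#> high  low
#>  109   91
```

109/200 = 54.5% of cells activated CDK4/6 persistently after mitogen
release — a draw around the generator's default activating probability of
0.54. The event table orders the landmarks the way the biology does
(CDK4/6-on, then CDK2-on, then APC/C-off; non-activating cells have no
events):

```r
head(events, 3)
#> # A tibble: 3 x 5
#>   cell_id   t_cdk46_on t_cdk2_on t_apc_off t_anaphase_ref
#>   <chr>          <dbl>     <dbl>     <dbl>          <dbl>
#> 1 cell_0001       NA        NA        NA               NA
#> 2 cell_0002       NA        NA        NA               NA
#> 3 cell_0003       13.6      14.8      17.2             NA
```

Estimating the CDK2 contamination fraction from a simulated
CDK4/6-inhibition experiment (truth: 0.35):

```r
inhibited <- apply_perturbation(
  simulate_quiescence_release(
    generator_params(n_cells = 260, p_activate = 1, noise_sd = 0.02, seed = 1)),
  perturbation_spec("cdk46_inhibitor", t_add = 20))
estimate_correction_factor(inhibited, window = 4)
#> <correction_fit>
#>   f_hat    = 0.3480 (se 0.0009)
#>   points   = 4826 from 254 S/G2 cells, window [20, 24] h
#>   flatness = 0.00024 activity/h after correction
```

The near-zero flatness says the corrected signal is essentially constant
after inhibition — the criterion by which the correction factor is
defined.

A YAML-config pipeline (`run_simulate()` / `run_analyze()`, with a thin
CLI wrapper in `inst/scripts/cdktrace-cli.R`) ties simulation and analysis
together and writes events, fates, cumulative curves, stress bin tables
and a resolved-config copy next to the outputs.

## Package layout

| | |
|---|---|
| `R/synth-*.R` | generator parameters, simulators, perturbations |
| `R/correction.R` | corrected activity and the regression estimator |
| `R/events.R` | onset / degron-rise detection, phase labels |
| `R/classify.R` | fate classifiers, mixture thresholding, bimodality |
| `R/cohort-stats.R` | alignment, cumulative curves, bootstrap bands, stress bins, Rb matching |
| `R/pipeline.R` | config-driven simulate/analyze entry points |
| `vignettes/cdktrace-methods.Rmd` | the model, assumptions, and design choices |
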