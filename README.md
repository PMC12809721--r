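# synctap

Analysis pipeline for synchronization–continuation finger-tapping
experiments acquired during fMRI, written for researchers studying
sensorimotor timing: how quickly an internal timing model "tunes in"
to an external beat, what happens when the beat stops, and which brain
regions track moment-to-moment tapping error.

The task: in each trial participants tap a force sensor in time with
12 tones at a 500-ms inter-onset interval (synchronization, 6.5 s),
then keep tapping at the same rate without tones (continuation, 20 s),
followed by stop, passive listening, and rest periods. Three runs of
six trials are scanned at TR = 1 s (345 volumes per run).

The package covers the full chain:

* **paradigm** — the deterministic trial/phase/tone timeline, BIDS-style
  `events.tsv` export, and the early/late phase boundaries
  (Sync1 0–2.5 s, Sync2 2.5–6 s, Cont1 6–7.5 s, Cont2 7.5–26 s).
* **simulate** — a calibrated generative model standing in for
  non-shareable participant data: a two-level timekeeper
  (Var(ITI) = σ²_T + 2σ²_M, lag-one autocovariance −σ²_M) with linear
  phase correction (gain α), tuning-in and continuation-onset
  transients, force-pulse rendering, artifact planting and AR(1) BOLD
  synthesis, all reproducible from one master seed.
* **tapdetect** — zero-phase filtering, peak-based tap detection with
  auditable exclusion flags (500-a.u. force floor, first-tap reaction
  exclusion, 250–1000-ms interval validity).
* **behavior** — sliding-window moving averages
  (x̄_SMA,t(n) = Σw_t(n)/N_t(n), 2-s window every 0.5 s), event-based
  (n-th tap) averaging, condition/phase cell summaries with CV = SD/mean,
  covariate residualization, repeated-measures ANOVA with Tukey–Kramer
  post-hocs.
* **glm** — six-regressor block GLM (double-gamma HRF, temporal
  derivatives, 90-s high-pass, AR(1) prewhitening), contrasts,
  inverse-variance run combination, and group cluster inference by
  sign-flip permutation at Z > 3.1.
* **fircorr** — FIR deconvolution of the 26-s trial response (26 1-s
  bins), 0.5-s upsampling, voxelwise lagged correlation of
  |SMA ITI − 500| with the response at haemodynamic delays 0–6 s, and
  max-statistic permutation inference with covariates.

## Worked example

Simulate a small cohort, run detection and aggregation, and test the
condition difference:

```r
library(synctap)
coh <- make_cohort(12, seed = 42)      # 12 subjects x 3 runs x 6 trials
res <- analyze_cohort_behavior(coh)    # detect taps, exclude, aggregate
res$summary
#>   level mean_iti sd_iti mean_cv    sd_cv n_subjects
#> 1  sync    493.8  4.001 0.05629 0.012162         12
#> 2  cont    500.6 11.217 0.05593 0.008531         12
#> 3 sync1    488.0  7.268 0.05127 0.008049         12
#> 4 sync2    497.0  4.550 0.05444 0.014321         12
#> 5 cont1    504.9 10.746 0.05176 0.018494         12
#> 6 cont2    500.3 11.301 0.05457 0.007367         12
res$exclusions
#>  weak_force   first_tap out_of_task    fast_iti  missed_iti
#>          18         215           0          26          24
```

The group mean inter-tap interval is below the 500-ms target during
synchronization (taps lock to the tones after an early fast-tapping
transient: Sync1 < Sync2) and above it during continuation, with the
transient slowing at continuation onset visible as Cont1 > Cont2. The
exclusion counts mirror the planted simulator artifacts: one reactive
first tap per trial, weak presses under the 500-a.u. floor, and
fast/missed intervals outside 250–1000 ms.

```r
cells <- res$cells
an <- rm_anova(cells[cells$phase == "all", ], dv = "mean_iti",
               factors = c("condition", "run"))
an
#> repeated-measures ANOVA (12 subjects)
#>          effect df1 df2      F       p
#> 1     condition   1  11 9.3277 0.01097
#> 2           run   2  22 1.1359 0.33925
#> 3 condition:run   2  22 0.8808 0.42857
an$posthoc$condition
#>   level1 level2 diff    q p_adj
#> 1   cont   sync 6.85 4.32 0.011
```

Even at n = 12 the condition effect (continuation ≈ 7 ms slower than
synchronization) is detected; at the full cohort size of 100 it is
unambiguous.

For the imaging side, `build_design()` / `fit_glm()` /
`contrast_map()` / `combine_runs_fixed_effects()` / `group_stats()`
implement the block analysis, and `build_fir_design()` / `fit_fir()` /
`upsample_betas()` / `lagged_correlation()` / `group_permutation()`
the lagged brain–behaviour analysis; the methods vignette
(`vignettes/synctap-methods.Rmd`) walks through the models, their
assumptions and every calibrated default.

A thin command-line wrapper is installed at `inst/exec/synctap`:

```sh
Rscript inst/exec/synctap simulate-cohort --out ds --seed 7
Rscript inst/exec/synctap detect   --out ds
Rscript inst/exec/synctap behavior --out ds
```

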