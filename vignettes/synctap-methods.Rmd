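---
title: "Methods: models, calibration and inference in synctap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and inference in synctap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synctap)
```

# The task and its timeline

`synctap` analyses a paced finger-tapping experiment performed during
fMRI. Each of three runs contains a 324-s main task block of six 54-s
trials; a trial cycles through synchronization (6.5 s of tone-paced
tapping, 12 tones of 100 ms at 1 kHz with a 500-ms inter-onset
interval), continuation (20 s of self-paced tapping at the same rate),
a 1-s stop instruction, 6.5 s of passive listening, and 20 s of rest.
With pre-scan (6 s), preparation (2 s), ending (2 s) and post-scan
(11 s) segments the run spans 345 volumes at TR = 1 s.

```{r}
tl <- run_timeline()
tl
head(events_table(tl))
```

Within a trial, behaviour and brain responses are analysed on the
26-s synchronization-plus-continuation window. Two boundary
conventions coexist and are carried explicitly as `mode` throughout:
the *behavioural* windows end at 26 s (early synchronization 0–2.5 s,
late synchronization 2.5–6 s, early continuation 6–7.5 s, late
continuation 7.5–26 s), while the *regressor* convention extends late
continuation to 26.5 s and adds stop/listen (26.5–34 s) and rest
(34–54 s). All intervals are half-open `[a, b)` so every instant maps
to exactly one phase; the first tone is placed at synchronization
onset, leaving the final 0.9 s of the phase tone-free (the tone train
occupies [0, 5.6] s).

# The generative tapping model

Participant data for this task cannot be shared, so the package ships
a generative simulator whose defaults *are* the study conditions: 100
subjects, 3 runs of 6 trials, and group-level behaviour matching the
reference descriptive statistics. The model is a two-level timekeeper
(Wing–Kristofferson) with first-order linear phase correction:

* During synchronization the planned interval is
  $I_n = P + A\,e^{-t/\tau} + T_n$, where $P$ is the internal period
  (500 ms at the group level), $A$ (`sync_offset`) and $\tau$
  (`convergence_tau`, 0.9 s) describe the tuning-in transient, and
  $T_n \sim \mathcal N(0, \sigma_T^2)$ is timekeeper noise. The next
  planned tap subtracts $\alpha$ times the previous tap–tone
  asynchrony ($\alpha = 0.25$). Observed taps add motor noise
  $M_n \sim \mathcal N(0, \sigma_M^2)$, so observed intervals are
  $I_n + M_n - M_{n-1}$ — the classic variance decomposition
  $\mathrm{Var}(\mathrm{ITI}) = \sigma_T^2 + 2\sigma_M^2$ with lag-one
  autocovariance $-\sigma_M^2$, which the test suite verifies by
  Monte-Carlo against the closed form.
* The first tap of a trial is reactive: it follows tone one after a
  short latency (60 ± 30 ms, truncated at zero). Because participants
  are cued by the trial structure, this latency is well below a naive
  auditory reaction time; with a ~150-ms latency the correction
  transient alone would drive early intervals far below the observed
  490 ms. The analysis always excludes this tap.
* During continuation there are no tones and no correction; the period
  becomes $P + c + B\,e^{-(t-6)/d} + W_t + T_n$ with a steady offset
  $c$ (7.0 ms — continuation is slightly slow), a transient
  lengthening at continuation onset ($B = 9.5$ ms decaying with
  $d = 0.6$ s — the perturbation when the tones stop), and a slow
  random-walk drift $W_t$ (3.5 ms per interval) reflecting the loss of
  external pacing; the drift makes continuation more variable than
  synchronization, as observed.
* Artifacts are planted at low rates (misses 0.2 %, extra taps 0.2 %,
  weak taps 0.3 %) and recorded as ground truth. The rates are
  deliberately small: a missed tap during synchronization leaves a
  ~940-ms gap that passes the 1000-ms validity bound and biases both
  the mean and the CV, so a cohort with few-percent artifact rates
  could not show the reference group statistics; in clean cohorts of
  engaged neurotypical tappers, unusable trials are on the order of one
  per cent.

## Calibration

The noise magnitudes and transient parameters ($A$, $\tau$, $B$, $c$,
$\sigma_T$; $\sigma_M = 12$ ms fixed) were calibrated once so that the
**full pipeline** — force synthesis, detection, exclusion rules, cell
aggregation — reproduces the group descriptive statistics of the task
(synchronization mean ITI 496.95 ms, continuation 507.36 ms, early
continuation 511.16 ms, synchronization CV 0.057) in expectation over
cohorts. Calibration used Newton iterations on Monte-Carlo estimates
with common random numbers; the result is frozen into
`tapping_params()`. The reference condition means and phase means come
from different cell weightings and are not jointly attainable; the
calibration prioritises the condition means, the early-continuation
mean and the synchronization CV, and preserves the phase orderings
(early synchronization faster than late; early continuation slower
than late). The calibrated `sync_offset` is ≈ +1.8 ms, i.e. nearly
zero: under the calibrated gain, the early-synchronization speed-up
emerges from phase correction of the reactive first tap rather than
from a fast initial period.

Between-subject variation enters through the internal period
(SD 12 ms), the initial offset (SD 30 ms), the correction gain
(SD 0.06) and the tuning-in constant (SD 0.12 s). This partitioning is
a simulator choice — no within-subject variance decomposition is
available to match. It yields a subject-level synchronization-mean SD
of ≈ 4 ms and continuation ≈ 12 ms, smaller than the reference ±32 ms,
which summarises spread over subject × run × trial cells, not over
subject means.

## Force traces

Taps are rendered at 1 kHz as a sharp impact transient peaking at the
tap onset (exponential rise 4 ms, decay 12 ms — the rise-to-peak is
below the 5-ms resolution the detector assumes) plus a broad
secondary bump (~200 ms wide, 35 % amplitude, 80 ms later) from finger
inertia and pulp viscoelasticity. Amplitudes are lognormal (mean
5000 a.u., CV 0.25), far above the 500-a.u. exclusion floor;
weak-artifact taps are drawn at 80–350 a.u. Gaussian sensor noise
(SD 20 a.u.) and a slow sinusoidal baseline drift complete the trace.

# Tap detection and exclusion rules

The raw trace is zero-phase filtered (2nd-order Butterworth, high-pass
10 Hz by default, forward-backward) — this removes drift while leaving
the impact transient, and hence peak timing, intact. Candidate taps
are local maxima above a noise-adaptive threshold (median + 5 robust
SDs of the whole trace); a 125-ms refractory gap keeps the larger peak
of any close pair, which suppresses both the secondary bump and the
filter's ringing side-lobes while staying below the 250-ms fast-tap
bound. The tap onset is the impact-peak time; peak force is the
maximum within 125 ms of onset.

Exclusions are flags, never deletions, so counts are auditable: peaks
below 500 a.u. are `weak_force`; the first tap of each trial is
`first_tap` (reaction, not synchronization); detections outside the
26-s tapping window are `out_of_task`. Inter-tap intervals are
computed between successive included taps, timestamped at the second
tap of the pair (a convention the sliding-window average needs;
configurable), and intervals outside [250, 1000] ms are flagged
invalid (fast/missed taps). On artifact-free synthetic runs detection
is exact: precision = recall = 1 with mean onset error ≈ 0.25 ms.

# Behavioural statistics

The sliding-window moving average (SMA) computes, for every grid time
$t(n)$ (1–26 s in 0.5-s steps), the mean of valid samples within
$|t - t(n)| \le W$ with $W = 1$ s — a 2-s window holding 4–5 taps.
Membership is closed on both sides, empty windows are missing, and the
implementation is tested for exact equality with a brute-force
window-membership oracle on random series. An event-based (n-th tap)
averaging alternative aligns each subject's n-th interval with the
$n \times 500$-ms point; both methods agree on the phase-mean
orderings, while the index-aligned curve drifts off wall-clock time
for subjects tapping off-rate.

Cell summaries (subject × condition × phase × run × trial means and
CVs) use raw valid samples within the phase windows; the SMA curve is
used for dynamics and for the brain–behaviour series. Group summaries
collapse cells to subject means (unweighted over available cells) and
then across subjects.

Covariates (age, sex) are regressed out of cell metrics by least
squares, keeping the grand mean. The repeated-measures ANOVA is the
classical within-subject decomposition
`dv ~ f1*f2*... + Error(subject/(f1*f2*...))` on subject-cell means
(unweighted means over available cells; subjects missing a cell are
dropped for that test and reported). Post-hoc pairwise comparisons use
the Tukey–Kramer studentized-range criterion on the matching error
stratum. Its type-I rate is verified at the nominal 5 % over 500 null
replicates.

# First-level GLM and group inference

The block design contains six HRF-convolved boxcars (Sync1, Sync2,
Cont1, Cont2, StopListen, Rest; regressor-mode boundaries), their
temporal derivatives, a discrete-cosine high-pass basis (cutoff 90 s)
and an intercept; estimation is restricted to the 324 task-block
volumes. The HRF is the canonical double gamma (6-s response peak,
16-s undershoot, 1:6 ratio), and the convolution is verified against
an independent Riemann-sum oracle. Prewhitening is a two-pass
Prais-Winsten/Cochrane–Orcutt scheme: per-voxel residual lag-one
autocorrelation, pooled into 0.05-wide bins, quasi-differencing, and a
refit — on AR(1) noise the null contrast Z statistics are standard
normal by a Kolmogorov–Smirnov check. Contrasts are linear functionals
with Z from the exact t tail probability (log-scale, no saturation).
Per-run maps combine across runs by inverse-variance (fixed-effects)
weighting, tested against the closed form.

Group analysis is a one-sample test of subject effect maps after
regressing out centred covariates, thresholded at Z > 3.1, with
cluster-extent family-wise error control by sign-flip permutation of
the maximum cluster size (6-connectivity components via union-find,
cross-checked against a flood-fill oracle). On desk-scale grids at
Z > 3.1 the extent null concentrates on sizes {0, 1}, so the discrete
test is valid but strictly conservative; the error-control calibration
therefore uses spatially smoothed null maps (as real smoothed fMRI
data would be) and a z = 2.3 forming threshold, where the measured
family-wise rate sits at its nominal 5 % within binomial bounds.

# FIR deconvolution and lagged brain-behaviour correlation

The 26-s trial window is modelled with 26 one-second FIR bins
time-locked to synchronization onset (each task volume inside a
trial's window loads exactly one bin; each bin collects one volume per
trial), plus listen (7.5 s) and rest (20 s) nuisance boxcars, the 90-s
high-pass basis and an intercept. Bin estimates are linearly upsampled
to a 0.5-s grid (endpoints preserved, midpoints are bin-pair means).

The behavioural series is the subject-run SMA curve converted to a
deviation measure — |SMA ITI − 500| ms, or the absolute within-series
z score for force — so larger always means worse. For haemodynamic
lags 0–6 s (1-s steps, configurable to 0.5 s), the deviation at time
$t$ is Pearson-correlated with the upsampled response at $t + \delta$
over the overlapping support (missing points pairwise-excluded, at
least 10 pairs per lag), correlations are averaged across runs, Fisher
z-transformed, adjusted for covariates (age, sex, framewise
displacement), and tested by one-sample sign-flip permutation with
max-|t| family-wise error control across voxels and lags. The choice
of trial-pooled (rather than per-trial) behaviour series and of
Fisher-z after run averaging follows the simplest reading of the
source design; FIR bins are disjoint indicators and are left
unorthogonalised. An end-to-end recovery test plants a coupled region
at a 4-s delay and requires significant positive correlations only
inside the region at middle lags, with no spurious negative coupling.

# Numerical and engineering choices

* Determinism: every cohort draw derives from a master seed through a
  fixed integer scheme (`cohort_seeds()`, all seeds below $2^{31}$);
  identical configurations give byte-identical datasets.
* Trial assignment of detections uses a 2-ms grace at trial boundaries
  so peak jitter cannot push a boundary tap into the wrong trial.
* When a trial's physically first tap is excluded as weak, no further
  reaction exclusion is applied — the next tap is the trial's second
  tap, not a reaction.
* Empty windows, empty trials, all-zero maps, rank-deficient covariate
  designs, singular design matrices and sub-Nyquist filter cutoffs all
  raise explicit errors or produce flagged missing values rather than
  silent results.

# Problem sizes in the shipped tests

The acceptance suite simulates one 100-subject cohort (3 runs × 6
trials each, forces at 1 kHz) for parameter recovery; error-control
calibrations use 500 ANOVA replicates and 200 imaging replicates at
500 sign flips on 12×12×6 and smaller grids; coupling recovery uses 10
subjects on an 8×8×4 grid with 1000 permutations. These sizes keep the
whole suite within a few minutes on one CPU while leaving the
Monte-Carlo error well inside each assertion's tolerance.

# What passing tests do and do not show

The simulator reproduces the timing structure, exclusion pathology and
group-level statistics the analysis assumes, with white sensor noise,
a small rectangular BOLD grid, stationary AR(1) noise and no
physiological (cardiac/respiratory) or scanner-acoustic interference.
Passing tests therefore demonstrate that the estimators are correct
and calibrated under the stated model — not that the model captures
every property of real force sensors or real BOLD data (no
neurovascular modelling, no registration or brain geometry, no
slice-timing effects). Hemodynamic delay is treated as a discrete lag
grid; regional variation in true delay blurs, rather than shifts, the
recovered correlation profile.
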