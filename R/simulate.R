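#' Parameters of the generative tapping model
#'
#' The simulator uses a two-level timekeeper (central interval generator
#' plus peripheral motor delay) with first-order linear phase correction
#' during tone-paced tapping. Planned inter-onset intervals during
#' synchronization are
#' \deqn{I_n = P + A e^{-t/\tau} + T_n,}
#' where `P` is the target period, `A` (`sync_offset`, negative = initially
#' faster tapping) decays with time constant `tau` as the internal model
#' tunes in, and `T_n` is timekeeper noise. Each planned tap is additionally
#' corrected by `-alpha` times the previous tap-tone asynchrony, and the
#' observed tap adds motor noise `M_n`, so observed intervals carry the
#' classic negative lag-one autocovariance `-sigma_motor^2`. During
#' continuation there are no tones and no correction; the period becomes
#' `P + cont_steady_offset + cont_perturbation * exp(-(t - 6)/cont_decay)`
#' (a transient lengthening when the tones stop) plus a slow random-walk
#' drift of the timekeeper (`cont_drift_sd` per interval), reflecting the
#' loss of external pacing.
#'
#' Defaults are calibrated so that the full detection-plus-aggregation
#' pipeline run on a default cohort reproduces the group condition and
#' phase means the task is known to produce (sync ~497 ms with early
#' synchronization faster than late, continuation ~507 ms with early
#' continuation slower than late, synchronization CV of ITI ~0.057).
#'
#' @param target_period target inter-tap interval, ms.
#' @param sync_offset initial synchronization period bias, ms.
#' @param convergence_tau time constant of the tuning-in decay, s.
#' @param alpha phase-correction gain, must lie in (0, 2).
#' @param reaction_mean,reaction_sd reaction time of the first (reactive)
#'   tap after tone one, ms.
#' @param sigma_timekeeper,sigma_motor timekeeper and motor noise SDs, ms.
#' @param cont_perturbation transient period lengthening at continuation
#'   onset, ms.
#' @param cont_decay decay constant of that transient, s.
#' @param cont_steady_offset steady continuation period minus the target,
#'   ms.
#' @param cont_drift_sd per-interval SD of the continuation period random
#'   walk, ms.
#' @param miss_rate,extra_rate,weak_rate probabilities of planted
#'   artifacts: omitted taps, inserted extra taps, and taps too weak to
#'   pass the force floor.
#' @param seed optional integer; when set, [simulate_tapping()] seeds its
#'   own RNG stream.
#' @return list of class `tapping_params`.
#' @export
tapping_params <- function(target_period = 500,
                           sync_offset = 1.8,
                           convergence_tau = 0.9,
                           alpha = 0.25,
                           reaction_mean = 60,
                           reaction_sd = 30,
                           sigma_timekeeper = 12.22,
                           sigma_motor = 12,
                           cont_perturbation = 9.5,
                           cont_decay = 0.6,
                           cont_steady_offset = 7.0,
                           cont_drift_sd = 3.5,
                           miss_rate = 0.002,
                           extra_rate = 0.002,
                           weak_rate = 0.003,
                           seed = NULL) {
  p <- list(target_period = target_period, sync_offset = sync_offset,
            convergence_tau = convergence_tau, alpha = alpha,
            reaction_mean = reaction_mean, reaction_sd = reaction_sd,
            sigma_timekeeper = sigma_timekeeper, sigma_motor = sigma_motor,
            cont_perturbation = cont_perturbation, cont_decay = cont_decay,
            cont_steady_offset = cont_steady_offset,
            cont_drift_sd = cont_drift_sd, miss_rate = miss_rate,
            extra_rate = extra_rate, weak_rate = weak_rate, seed = seed)
  if (!(p$alpha > 0 && p$alpha < 2)) {
    stop("alpha must lie in (0, 2): the phase-correction loop is ",
         "otherwise unstable", call. = FALSE)
  }
  if (p$sigma_timekeeper < 0 || p$sigma_motor < 0 || p$reaction_sd < 0 ||
      p$cont_drift_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  rates <- c(p$miss_rate, p$extra_rate, p$weak_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("artifact rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (p$convergence_tau <= 0 || p$cont_decay <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  class(p) <- "tapping_params"
  p
}

#' Simulate intended tap times for one run
#'
#' Generates the ground-truth tap sequence of every trial in `timeline`
#' under the model described in [tapping_params()]. Taps are paced by the
#' trial's tones while tones remain (tap n is paired with tone n), then
#' continue self-paced until the end of the 26-s tapping period. Artifacts
#' are planted afterwards: missed taps are removed from the record (kept in
#' the `missed` attribute for audit), extra taps are inserted inside a
#' random interval, and weak taps are labelled so the force renderer draws
#' their amplitude below the detection floor.
#'
#' @param timeline a [run_timeline()].
#' @param params a [tapping_params()].
#' @return data.frame of class `tap_record` with columns `trial`, `onset`
#'   (seconds from the trial's synchronization onset), `label`
#'   (`"normal"`, `"extra"`, `"weak"`); attribute `missed` holds the
#'   removed taps. Deterministic given the RNG state (or `params$seed`).
#' @export
simulate_tapping <- function(timeline, params = tapping_params()) {
  stopifnot(inherits(timeline, "run_timeline"))
  if (!inherits(params, "tapping_params")) {
    params <- do.call(tapping_params, params)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  n_tones <- timeline$n_tones
  tone_s <- timeline$tone_onsets
  period_s <- p$target_period / 1000
  t_end <- 26

  sim_trial <- function(trial) {
    max_taps <- ceiling(t_end / period_s * 2) + 10
    planned <- numeric(max_taps)
    observed <- numeric(max_taps)
    planned[1] <- max(0, (p$reaction_mean +
                          stats::rnorm(1, 0, p$reaction_sd)) / 1000)
    observed[1] <- max(0, planned[1] +
                         stats::rnorm(1, 0, p$sigma_motor) / 1000)
    drift <- 0
    n <- 1
    repeat {
      t_now <- planned[n]
      if (n < n_tones) {
        interval <- p$target_period +
          p$sync_offset * exp(-t_now / p$convergence_tau) +
          stats::rnorm(1, 0, p$sigma_timekeeper)
        corr <- p$alpha * (observed[n] - tone_s[n])
        nxt <- t_now + interval / 1000 - corr
      } else {
        t_land <- t_now + period_s
        pert <- p$cont_perturbation *
          exp(-max(0, t_land - 6) / p$cont_decay)
        drift <- drift + stats::rnorm(1, 0, p$cont_drift_sd)
        interval <- p$target_period + p$cont_steady_offset + pert + drift +
          stats::rnorm(1, 0, p$sigma_timekeeper)
        nxt <- t_now + interval / 1000
      }
      obs <- nxt + stats::rnorm(1, 0, p$sigma_motor) / 1000
      if (nxt >= t_end || obs >= t_end || n + 1 > max_taps) break
      n <- n + 1
      planned[n] <- nxt
      observed[n] <- obs
    }
    data.frame(trial = trial, onset = observed[seq_len(n)],
               label = "normal", stringsAsFactors = FALSE)
  }

  taps <- do.call(rbind, lapply(seq_len(timeline$n_trials), sim_trial))

  missed <- taps[0, ]
  out <- vector("list", timeline$n_trials)
  for (k in seq_len(timeline$n_trials)) {
    tt <- taps[taps$trial == k, ]
    n <- nrow(tt)
    # misses: never the first tap, so the reactive tap stays in place
    if (p$miss_rate > 0 && n > 2) {
      drop <- which(stats::runif(n - 1) < p$miss_rate) + 1L
      if (length(drop)) {
        missed <- rbind(missed, tt[drop, ])
        tt <- tt[-drop, ]
        n <- nrow(tt)
      }
    }
    if (p$extra_rate > 0 && n > 1) {
      ins <- which(stats::runif(n - 1) < p$extra_rate)
      if (length(ins)) {
        frac <- stats::runif(length(ins), 0.2, 0.8)
        extra <- data.frame(
          trial = k,
          onset = tt$onset[ins] + frac * diff(tt$onset)[ins],
          label = "extra", stringsAsFactors = FALSE)
        tt <- rbind(tt, extra)
        tt <- tt[order(tt$onset), ]
        n <- nrow(tt)
      }
    }
    if (p$weak_rate > 0 && n > 0) {
      wk <- stats::runif(n) < p$weak_rate
      tt$label[wk & tt$label == "normal"] <- "weak"
    }
    out[[k]] <- tt
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  attr(rec, "missed") <- missed
  attr(rec, "params") <- params
  class(rec) <- c("tap_record", class(rec))
  rec
}

#' Parameters of the force-trace renderer
#'
#' Each tap is rendered as a sharp impact transient peaking at the tap
#' onset (the rise from baseline to peak is a few milliseconds) followed by
#' a broader (~200 ms) secondary bump from finger inertia and pulp
#' viscoelasticity. Peak amplitudes are lognormal (positive,
#' right-skewed); the arbitrary-unit scale puts typical peaks near 5000
#' a.u., well above the 500 a.u. exclusion floor, while weak-artifact taps
#' are drawn below the floor.
#'
#' @param sampling_rate samples per second; at least 200 Hz is required to
#'   resolve the impact transient.
#' @param impact_rise_ms,impact_decay_ms exponential rise/decay constants
#'   of the impact peak, ms.
#' @param second_peak_delay_ms,second_peak_width_ms,second_peak_gain
#'   latency, full width and relative amplitude of the inertial bump.
#' @param peak_amplitude_mean,peak_amplitude_cv lognormal amplitude
#'   distribution of normal taps, a.u.
#' @param weak_amplitude_range amplitude range for weak-artifact taps,
#'   a.u.; the upper end sits below the 500 a.u. floor.
#' @param baseline_noise_sd Gaussian sensor noise SD, a.u.
#' @param baseline_drift_amp,baseline_drift_freq slow sinusoidal baseline
#'   drift (a.u., Hz) removed by the high-pass filter.
#' @return list of class `force_params`.
#' @export
force_params <- function(sampling_rate = 1000,
                         impact_rise_ms = 4,
                         impact_decay_ms = 12,
                         second_peak_delay_ms = 80,
                         second_peak_width_ms = 200,
                         second_peak_gain = 0.35,
                         peak_amplitude_mean = 5000,
                         peak_amplitude_cv = 0.25,
                         weak_amplitude_range = c(80, 350),
                         baseline_noise_sd = 20,
                         baseline_drift_amp = 50,
                         baseline_drift_freq = 0.2) {
  p <- as.list(environment())
  if (p$sampling_rate < 200) {
    stop("sampling_rate below 200 Hz cannot resolve the impact peak",
         call. = FALSE)
  }
  if (p$impact_rise_ms <= 0 || p$impact_decay_ms <= 0 ||
      p$second_peak_width_ms <= 0) {
    stop("pulse widths must be positive", call. = FALSE)
  }
  class(p) <- "force_params"
  p
}

#' Draw peak forces for a tap record
#'
#' Normal and extra taps get lognormal amplitudes; weak-artifact taps are
#' drawn uniformly below the detection floor.
#'
#' @param taps a `tap_record`.
#' @param params a [force_params()].
#' @return the record with a `force` column (a.u.).
#' @export
draw_tap_forces <- function(taps, params = force_params()) {
  n <- nrow(taps)
  cv <- params$peak_amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(params$peak_amplitude_mean) - sdlog^2 / 2
  force <- stats::rlnorm(n, meanlog, sdlog)
  weak <- taps$label == "weak"
  force[weak] <- stats::runif(sum(weak), params$weak_amplitude_range[1],
                              params$weak_amplitude_range[2])
  taps$force <- force
  taps
}

#' Render a tap record as a sampled force trace
#'
#' @param taps a `tap_record` with a `force` column (see
#'   [draw_tap_forces()]); records without forces get them drawn from the
#'   current RNG stream.
#' @param timeline the [run_timeline()] the taps belong to; tap onsets are
#'   trial-relative and are placed at `trial_onset + onset` in run time.
#' @param params a [force_params()].
#' @return object of class `force_trace`: list with `values` (a.u.),
#'   `sampling_rate`, `run_index` and implicit time origin at the start of
#'   the scan.
#' @export
simulate_force_trace <- function(taps, timeline, params = force_params()) {
  stopifnot(inherits(timeline, "run_timeline"))
  if (is.null(taps$force)) taps <- draw_tap_forces(taps, params)
  fs <- params$sampling_rate
  n <- as.integer(round(timeline$run_duration * fs))
  dt_ms <- 1000 / fs
  kt <- seq(-5 * params$impact_rise_ms,
            params$second_peak_delay_ms + 2 * params$second_peak_width_ms,
            by = dt_ms)
  impact <- ifelse(kt <= 0, exp(kt / params$impact_rise_ms),
                   exp(-kt / params$impact_decay_ms))
  sigma2 <- params$second_peak_width_ms / 4
  bump <- params$second_peak_gain *
    exp(-(kt - params$second_peak_delay_ms)^2 / (2 * sigma2^2))
  kernel <- impact + bump
  koff <- which.max(kernel) - 1L  # samples before the peak

  tvec <- (seq_len(n) - 1) / fs
  values <- stats::rnorm(n, 0, params$baseline_noise_sd) +
    params$baseline_drift_amp *
      sin(2 * pi * params$baseline_drift_freq * tvec)

  run_onsets <- timeline$trial_onsets[taps$trial] + taps$onset
  idx0 <- round(run_onsets * fs) - koff
  for (i in seq_along(idx0)) {
    ii <- idx0[i] + seq_along(kernel)
    keep <- ii >= 1 & ii <= n
    values[ii[keep]] <- values[ii[keep]] + taps$force[i] * kernel[keep]
  }
  structure(list(values = values, sampling_rate = fs,
                 run_index = timeline$run_index),
            class = "force_trace")
}

#' Parameters of the synthetic BOLD generator
#'
#' Voxel time series are a sum of scaled effect regressors inside given
#' masks plus stationary AR(1) noise. The grid is deliberately small (the
#' generator is a test bed for the estimators, not a brain phantom).
#'
#' @param grid voxel dimensions.
#' @param noise_sd marginal SD of the AR(1) noise.
#' @param ar1 lag-one autocorrelation, |ar1| < 1.
#' @param effects list of effects, each a list with `mask` (logical array
#'   matching `grid` or a vector of voxel indices), `ts` (numeric regressor
#'   of length `n_volumes`), and `amplitude`.
#' @return list of class `bold_params`.
#' @export
bold_params <- function(grid = c(20, 20, 12), noise_sd = 1, ar1 = 0.3,
                        effects = list()) {
  if (abs(ar1) >= 1) stop("|ar1| must be < 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(grid = as.integer(grid), noise_sd = noise_sd, ar1 = ar1,
                 effects = effects), class = "bold_params")
}

#' Simulate a 4D BOLD run
#'
#' @param timeline a [run_timeline()]; supplies `n_volumes` and TR.
#' @param params a [bold_params()].
#' @return object of class `volume_series`: list with `data` (4D array,
#'   x-y-z-time) and `tr`.
#' @export
simulate_bold <- function(timeline, params = bold_params()) {
  stopifnot(inherits(timeline, "run_timeline"))
  nt <- timeline$n_volumes
  nv <- prod(params$grid)
  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1^2)
    y <- matrix(stats::rnorm(nt * nv, 0, innov_sd), nrow = nt)
    if (params$ar1 != 0) {
      y[1, ] <- y[1, ] / sqrt(1 - params$ar1^2)
      for (t in 2:nt) y[t, ] <- params$ar1 * y[t - 1, ] + y[t, ]
    }
  } else {
    y <- matrix(0, nrow = nt, ncol = nv)
  }
  for (ef in params$effects) {
    idx <- if (is.logical(ef$mask)) which(ef$mask) else as.integer(ef$mask)
    if (any(idx < 1 | idx > nv)) {
      stop("effect mask indices outside the voxel grid", call. = FALSE)
    }
    if (length(ef$ts) != nt) {
      stop("effect regressor length must equal n_volumes", call. = FALSE)
    }
    amp <- if (is.null(ef$amplitude)) 1 else ef$amplitude
    y[, idx] <- y[, idx] + amp * ef$ts
  }
  structure(list(data = array(t(y), dim = c(params$grid, nt)),
                 tr = timeline$tr),
            class = "volume_series")
}

#' Time-by-voxel matrix view of a volume series
#' @param vol a `volume_series` or 4D array.
#' @return numeric matrix, volumes in rows.
#' @export
vol_matrix <- function(vol) {
  a <- if (inherits(vol, "volume_series")) vol$data else vol
  d <- dim(a)
  t(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Cohort-level simulation parameters
#'
#' Subject-level tapping parameters are drawn around the group-level
#' generative means of [tapping_params()]: the internal period, the
#' initial synchronization bias, the correction gain and the tuning-in
#' constant vary across subjects, which propagates into between-subject
#' spread of the condition means. Covariates (age, sex, mean framewise
#' displacement) are drawn to resemble a young neurotypical adult cohort.
#'
#' @param tapping group-level [tapping_params()].
#' @param force a [force_params()].
#' @param bold a [bold_params()] used when BOLD volumes are requested.
#' @param period_sd,sync_offset_sd,alpha_sd,tau_sd between-subject SDs of
#'   the corresponding tapping parameters.
#' @param age_mean,age_sd,age_range,female_prob,fd_meanlog,fd_sdlog
#'   covariate generators.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(tapping = tapping_params(),
                          force = force_params(),
                          bold = bold_params(),
                          period_sd = 12,
                          sync_offset_sd = 30,
                          alpha_sd = 0.06,
                          tau_sd = 0.12,
                          age_mean = 22.86, age_sd = 4.29,
                          age_range = c(18, 39),
                          female_prob = 0.53,
                          fd_meanlog = log(0.15), fd_sdlog = 0.35) {
  structure(as.list(environment()), class = "cohort_params")
}

#' Per-subject, per-run RNG seeds derived from a master seed
#'
#' @param master integer master seed.
#' @param n_subjects,n_runs cohort dimensions.
#' @return integer matrix `n_subjects` x `n_runs + 1`; column 1 seeds the
#'   subject-level draws, the rest seed each run.
#' @export
cohort_seeds <- function(master, n_subjects, n_runs = 3) {
  m <- 2147483629
  s <- outer(seq_len(n_subjects) * 48611, 0:n_runs * 104729, `+`)
  matrix(as.integer((as.numeric(master) * 7919 + s) %% m),
         nrow = n_subjects)
}

#' Simulate a cohort of subjects
#'
#' Each subject gets parameters drawn around the group-level means and
#' `n_runs` runs of ground-truth taps, peak forces and (optionally)
#' rendered force traces and BOLD volumes. Fully reproducible: the master
#' seed determines every draw through [cohort_seeds()].
#'
#' @param n_subjects number of subjects (>= 1).
#' @param params a [cohort_params()].
#' @param seed master seed.
#' @param n_runs runs per subject.
#' @param traces render force traces (needed by the detection pipeline;
#'   disable for tests that only need ground-truth taps).
#' @param bold simulate BOLD volumes per run.
#' @return list of class `tap_cohort`; each element is a subject with
#'   `id`, `covariates`, `params` and `runs` (list with `timeline`,
#'   `taps`, and optionally `trace`, `bold`).
#' @export
make_cohort <- function(n_subjects, params = cohort_params(), seed = 1,
                        n_runs = 3, traces = TRUE, bold = FALSE) {
  stopifnot(n_subjects >= 1)
  seeds <- cohort_seeds(seed, n_subjects, n_runs)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i, 1])
    gp <- params$tapping
    sp <- gp
    sp$target_period <- gp$target_period +
      stats::rnorm(1, 0, params$period_sd)
    sp$sync_offset <- gp$sync_offset +
      stats::rnorm(1, 0, params$sync_offset_sd)
    sp$alpha <- min(0.9, max(0.05, gp$alpha +
                               stats::rnorm(1, 0, params$alpha_sd)))
    sp$convergence_tau <- max(0.2, gp$convergence_tau +
                                stats::rnorm(1, 0, params$tau_sd))
    sp$seed <- NULL
    sp <- do.call(tapping_params, sp[setdiff(names(sp), "seed")])
    age <- round(min(params$age_range[2], max(params$age_range[1],
      stats::rnorm(1, params$age_mean, params$age_sd))))
    covariates <- data.frame(
      age = age,
      sex = ifelse(stats::runif(1) < params$female_prob, "F", "M"),
      fd = stats::rlnorm(1, params$fd_meanlog, params$fd_sdlog),
      stringsAsFactors = FALSE)
    runs <- lapply(seq_len(n_runs), function(r) {
      set.seed(seeds[i, r + 1])
      tl <- run_timeline(run_index = r)
      taps <- simulate_tapping(tl, sp)
      taps <- draw_tap_forces(taps, params$force)
      run <- list(timeline = tl, taps = taps)
      if (traces) run$trace <- simulate_force_trace(taps, tl, params$force)
      if (bold) run$bold <- simulate_bold(tl, params$bold)
      run
    })
    list(id = sprintf("sub-%03d", i), covariates = covariates,
         params = sp, runs = runs)
  }) -> cohort
  class(cohort) <- "tap_cohort"
  cohort
}

#' Covariate table of a cohort
#' @param cohort a `tap_cohort`.
#' @return data.frame with one row per subject.
#' @export
cohort_covariates <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(s) {
    cbind(data.frame(subject = s$id, stringsAsFactors = FALSE),
          s$covariates)
  }))
  rownames(out) <- NULL
  out
}
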