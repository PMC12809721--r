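#' Zero-phase filter a force trace
#'
#' Applies a second-order Butterworth filter forwards and backwards
#' (`signal::filtfilt`), so tap onsets are not shifted. The default
#' follows the acquisition convention of high-pass filtering above 10 Hz,
#' which removes baseline drift and slow fluctuations while leaving the
#' sharp impact transient (and hence peak timing) intact; a low-pass
#' variant is available since detection is robust either way.
#'
#' @param trace a `force_trace`.
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param type `"high"` (default) or `"low"`.
#' @param order filter order.
#' @return filtered `force_trace` of identical length and rate.
#' @export
filter_trace <- function(trace, cutoff = 10, type = c("high", "low"),
                         order = 2) {
  type <- match.arg(type)
  stopifnot(inherits(trace, "force_trace"))
  nyq <- trace$sampling_rate / 2
  if (cutoff >= nyq) {
    stop("cutoff must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / nyq, type = type)
  out <- trace
  out$values <- as.numeric(signal::filtfilt(bf, trace$values))
  out$filtered <- c(trace$filtered, sprintf("%s-pass %g Hz", type, cutoff))
  out
}

#' Detect tap events in a force trace
#'
#' Tap candidates are local maxima of the trace above a noise-adaptive
#' detection threshold (`baseline + k_mad` robust SDs, with baseline and
#' spread taken as the median and MAD of the whole trace). The tap onset
#' is the time of the impact peak itself, since the rise from baseline to
#' peak lasts only a few milliseconds. Peak force is the maximum pressure
#' within `peak_window_ms` of the onset. A refractory gap of
#' `refractory_ms` between detections prevents the broad secondary bump of
#' the force pulse from being counted as a second tap while staying below
#' the 250-ms fast-tap limit, so genuinely fast taps are still detected
#' (and then excluded by the interval rule).
#'
#' Every exclusion is flagged rather than deleted: events below the
#' `force_floor` are flagged `weak_force`, the first tap of each trial is
#' flagged `first_tap` (it reflects reaction to the first tone rather than
#' synchronization), and detections outside any trial's 26-s tapping
#' period are flagged `out_of_task`.
#'
#' @param trace a `force_trace` (typically filtered, see
#'   [filter_trace()]).
#' @param timeline the [run_timeline()] used to assign taps to trials.
#' @param force_floor validity floor for peak force, a.u.
#' @param peak_window_ms window after onset searched for the peak force.
#' @param k_mad multiplier of the robust noise SD for the detection
#'   threshold.
#' @param refractory_ms minimum gap between successive detections.
#' @return data.frame of class `tap_events` with columns `run_time` (s
#'   from scan start), `trial`, `onset` (s from the trial's
#'   synchronization onset), `peak_force` and `flag` (one of `valid`,
#'   `first_tap`, `weak_force`, `out_of_task`). An empty trace raises an
#'   error; a trace with no suprathreshold samples returns zero rows.
#' @export
detect_taps <- function(trace, timeline, force_floor = 500,
                        peak_window_ms = 125, k_mad = 5,
                        refractory_ms = 125) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(timeline, "run_timeline"))
  x <- trace$values
  if (length(x) == 0) stop("empty force trace", call. = FALSE)
  fs <- trace$sampling_rate
  thr <- stats::median(x) + k_mad * stats::mad(x)

  above <- x > thr
  empty <- data.frame(run_time = numeric(0), trial = integer(0),
                      onset = numeric(0), peak_force = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("tap_events", class(empty))
  if (!any(above)) return(empty)

  # local maxima of suprathreshold runs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(j) {
    i <- starts[j]:ends[j]
    i[which.max(x[i])]
  }, integer(1))
  peaks <- sort(peaks)

  # enforce the refractory gap, keeping the larger peak of any close pair
  # (filter ringing produces small side lobes around each impact peak)
  gap <- as.integer(round(refractory_ms / 1000 * fs))
  ord <- order(x[peaks], decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(peaks[i] - accepted) >= gap)) {
      accepted <- c(accepted, peaks[i])
    }
  }
  peaks <- sort(accepted)

  win <- as.integer(round(peak_window_ms / 1000 * fs))
  n <- length(x)
  peak_force <- vapply(peaks, function(i) {
    max(x[i:min(n, i + win)])
  }, numeric(1))

  run_time <- (peaks - 1) / fs
  rel <- run_time - timeline$task_block_start
  # 2-ms grace so peak jitter at a trial boundary keeps the tap in its
  # trial
  trial <- floor((rel + 2e-3) / timeline$trial_duration) + 1
  trial[rel < 0 | trial > timeline$n_trials] <- NA
  onset <- run_time - timeline$trial_onsets[pmax(1L, ifelse(is.na(trial),
                                                            1L, trial))]
  onset[is.na(trial)] <- NA

  flag <- rep("valid", length(peaks))
  flag[is.na(trial) | onset >= 26] <- "out_of_task"
  flag[flag == "valid" & peak_force < force_floor] <- "weak_force"
  for (k in unique(trial[!is.na(trial)])) {
    in_trial <- which(!is.na(trial) & trial == k & flag != "out_of_task")
    if (length(in_trial)) {
      first <- in_trial[which.min(onset[in_trial])]
      if (flag[first] == "valid") flag[first] <- "first_tap"
    }
  }

  out <- data.frame(run_time = run_time, trial = as.integer(trial),
                    onset = onset, peak_force = peak_force, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("tap_events", class(out))
  out
}

#' Inter-tap-interval series from detected taps
#'
#' One sample per successive pair of included taps within a trial (taps
#' flagged `weak_force`, `first_tap` or `out_of_task` are excluded before
#' pairing, so the pair spanning the reactive first tap is dropped).
#' Intervals outside `bounds` are retained but flagged invalid: above the
#' upper bound they indicate a missed tap, below the lower bound a
#' spurious fast tap. The sample timestamp is the onset of the second tap
#' of the pair, which makes the series translation-invariant in value.
#'
#' @param events a `tap_events` data.frame.
#' @param bounds valid interval range in ms.
#' @return data.frame of class `measurement_series` (attribute `kind =
#'   "iti"`) with columns `trial`, `time` (s, trial-relative), `value`
#'   (ms) and `valid`. Trials with fewer than two included taps contribute
#'   no rows.
#' @export
compute_iti <- function(events, bounds = c(250, 1000)) {
  inc <- events[events$flag == "valid", , drop = FALSE]
  rows <- lapply(sort(unique(inc$trial)), function(k) {
    tt <- inc[inc$trial == k, , drop = FALSE]
    tt <- tt[order(tt$onset), , drop = FALSE]
    if (nrow(tt) < 2) return(NULL)
    iti <- diff(tt$onset) * 1000
    data.frame(trial = k, time = tt$onset[-1], value = iti,
               valid = iti >= bounds[1] & iti <= bounds[2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial = integer(0), time = numeric(0),
                      value = numeric(0), valid = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "kind") <- "iti"
  class(out) <- c("measurement_series", class(out))
  out
}

#' Peak-force series from detected taps
#'
#' One sample per included tap (weak, first and out-of-task taps are
#' excluded as in [compute_iti()]).
#'
#' @param events a `tap_events` data.frame.
#' @return `measurement_series` (attribute `kind = "force"`) with columns
#'   `trial`, `time`, `value` (a.u.), `valid` (all `TRUE`).
#' @export
compute_force_series <- function(events) {
  inc <- events[events$flag == "valid", , drop = FALSE]
  out <- data.frame(trial = inc$trial, time = inc$onset,
                    value = inc$peak_force, valid = TRUE)
  out <- out[order(out$trial, out$time), ]
  rownames(out) <- NULL
  attr(out, "kind") <- "force"
  class(out) <- c("measurement_series", class(out))
  out
}

#' Full detection pipeline for one run
#'
#' Filter, detect, and derive interval and force series; also tallies the
#' exclusions so they can be reported.
#'
#' @param trace raw `force_trace`.
#' @param timeline the run's [run_timeline()].
#' @param filter_cutoff high-pass cutoff, Hz (`NULL` skips filtering).
#' @param ... passed to [detect_taps()].
#' @return list with `events`, `iti`, `force` and `exclusions` (named
#'   counts).
#' @export
detect_run <- function(trace, timeline, filter_cutoff = 10, ...) {
  if (!is.null(filter_cutoff)) {
    trace <- filter_trace(trace, cutoff = filter_cutoff)
  }
  ev <- detect_taps(trace, timeline, ...)
  iti <- compute_iti(ev)
  force <- compute_force_series(ev)
  excl <- c(
    weak_force = sum(ev$flag == "weak_force"),
    first_tap = sum(ev$flag == "first_tap"),
    out_of_task = sum(ev$flag == "out_of_task"),
    fast_iti = sum(!iti$valid & iti$value < 250),
    missed_iti = sum(!iti$valid & iti$value > 1000)
  )
  list(events = ev, iti = iti, force = force, exclusions = excl)
}

#' Match detected taps to ground truth
#'
#' Greedy one-to-one matching within a tolerance, for simulator-based
#' validation of the detector.
#'
#' @param detected,truth data.frames with `trial` and `onset` columns.
#' @param tol_ms matching tolerance in ms.
#' @return list with `n_matched`, `precision`, `recall` and the mean
#'   absolute onset error (ms) of matched pairs.
#' @export
match_taps <- function(detected, truth, tol_ms = 5) {
  detected <- detected[!is.na(detected$onset) & !is.na(detected$trial), ,
                       drop = FALSE]
  n_match <- 0
  err <- numeric(0)
  for (k in unique(truth$trial)) {
    dt <- detected$onset[detected$trial == k]
    tr <- truth$onset[truth$trial == k]
    used <- logical(length(dt))
    for (t0 in tr) {
      d <- abs(dt - t0) * 1000
      d[used] <- Inf
      if (length(d) && min(d) <= tol_ms) {
        i <- which.min(d)
        used[i] <- TRUE
        n_match <- n_match + 1
        err <- c(err, min(d))
      }
    }
  }
  list(n_matched = n_match,
       precision = if (nrow(detected)) n_match / nrow(detected) else NA,
       recall = if (nrow(truth)) n_match / nrow(truth) else NA,
       mean_abs_error_ms = if (length(err)) mean(err) else NA)
}
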