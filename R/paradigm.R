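#' Default phase durations of the tapping task
#'
#' One trial of the task cycles through five phases: synchronization
#' (tone-paced tapping), continuation (self-paced tapping), a stop
#' instruction, passive listening, and rest. The default durations give a
#' 54-s trial; six trials tile the 324-s main task block of one run.
#'
#' @param sync,cont,stop,listen,rest phase durations in seconds.
#' @return data.frame with columns `phase` and `duration` (seconds), in
#'   presentation order.
#' @export
#' @examples
#' phase_specs()
phase_specs <- function(sync = 6.5, cont = 20, stop = 1, listen = 6.5,
                        rest = 20) {
  d <- c(sync = sync, cont = cont, stop = stop, listen = listen, rest = rest)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("all phase durations must be positive and finite", call. = FALSE)
  }
  data.frame(phase = names(d), duration = unname(d),
             stringsAsFactors = FALSE)
}

#' Build the deterministic timeline of one scanning run
#'
#' Lays out the run segments (pre-scan, preparation, main task block, task
#' ending, post-scan), the trial onsets within the task block, and the tone
#' onsets within each trial's synchronization phase. All downstream stages
#' (simulation, tap detection, GLM and FIR designs) take their timing from
#' this object. With the defaults, the task block lasts 6 x 54 = 324 s and
#' the run spans 345 volumes at TR = 1 s.
#'
#' Tones are placed at synchronization onset and every `ioi` seconds
#' thereafter, so the 12 default tones occupy [0, 5.6] s of the 6.5-s
#' synchronization phase (the trailing 0.9 s remains tone-free but still
#' belongs to synchronization).
#'
#' @param run_index 1-based run number (metadata).
#' @param phases phase durations as returned by [phase_specs()].
#' @param n_trials trials per run.
#' @param n_tones tones per synchronization phase.
#' @param ioi tone inter-onset interval, seconds.
#' @param tone_duration tone duration, seconds.
#' @param tone_freq tone frequency in Hz (metadata only).
#' @param tr repetition time of the fMRI acquisition, seconds.
#' @param segments named numeric vector with `pre_scan`, `prep`, `ending`
#'   and `post_scan` durations in seconds.
#' @return An object of class `run_timeline`: a list with the run geometry
#'   (`task_block_start`, `task_block_duration`, `trial_duration`,
#'   `trial_onsets` in run time, `tone_onsets` within-trial, `n_volumes`,
#'   `run_duration`, `tr`) plus the phase table.
#' @export
#' @examples
#' tl <- run_timeline()
#' tl$n_volumes          # 345
#' tl$task_block_duration # 324
run_timeline <- function(run_index = 1L, phases = phase_specs(),
                         n_trials = 6L, n_tones = 12L, ioi = 0.5,
                         tone_duration = 0.1, tone_freq = 1000, tr = 1,
                         segments = c(pre_scan = 6, prep = 2, ending = 2,
                                      post_scan = 11)) {
  stopifnot(is.data.frame(phases), all(c("phase", "duration") %in%
                                         names(phases)))
  if (any(phases$duration <= 0)) {
    stop("all phase durations must be positive", call. = FALSE)
  }
  if (n_trials < 1L || n_tones < 1L || ioi <= 0 || tr <= 0) {
    stop("n_trials, n_tones, ioi and tr must be positive", call. = FALSE)
  }
  needed <- c("pre_scan", "prep", "ending", "post_scan")
  if (!all(needed %in% names(segments))) {
    stop("segments must name pre_scan, prep, ending and post_scan",
         call. = FALSE)
  }
  trial_duration <- sum(phases$duration)
  sync_duration <- phases$duration[phases$phase == "sync"]
  last_tone_off <- (n_tones - 1L) * ioi + tone_duration
  if (last_tone_off > sync_duration) {
    stop("tone train does not fit inside the synchronization phase",
         call. = FALSE)
  }
  task_block_duration <- n_trials * trial_duration
  task_block_start <- unname(segments["pre_scan"] + segments["prep"])
  run_duration <- task_block_start + task_block_duration +
    unname(segments["ending"] + segments["post_scan"])
  n_volumes <- as.integer(round(run_duration / tr))

  ph_onsets <- cumsum(c(0, phases$duration[-nrow(phases)]))
  names(ph_onsets) <- phases$phase

  structure(list(
    run_index = as.integer(run_index),
    phases = phases,
    phase_onsets = ph_onsets,
    n_trials = as.integer(n_trials),
    trial_duration = trial_duration,
    trial_onsets = task_block_start + (seq_len(n_trials) - 1) *
      trial_duration,
    tone_onsets = (seq_len(n_tones) - 1) * ioi,
    n_tones = as.integer(n_tones),
    ioi = ioi,
    tone_duration = tone_duration,
    tone_freq = tone_freq,
    segments = segments,
    task_block_start = task_block_start,
    task_block_duration = task_block_duration,
    run_duration = run_duration,
    tr = tr,
    n_volumes = n_volumes
  ), class = "run_timeline")
}

#' @export
print.run_timeline <- function(x, ...) {
  cat(sprintf(
    "run_timeline: run %d, %d trials x %.1f s, task block %.0f s, %d volumes (TR %.2g s)\n",
    x$run_index, x$n_trials, x$trial_duration, x$task_block_duration,
    x$n_volumes, x$tr))
  invisible(x)
}

#' Export the timeline as a BIDS-style events table
#'
#' One row per phase instance (trial x phase) with onset, duration and
#' trial_type. Onsets are in run time, i.e. seconds from the start of the
#' scan, so the first synchronization onset equals the task-block start.
#'
#' @param timeline a [run_timeline()].
#' @return data.frame with columns `onset`, `duration`, `trial_type`,
#'   `trial`; rows ordered by onset.
#' @export
events_table <- function(timeline) {
  stopifnot(inherits(timeline, "run_timeline"))
  ph <- timeline$phases
  rows <- lapply(seq_len(timeline$n_trials), function(k) {
    data.frame(
      onset = timeline$trial_onsets[k] + timeline$phase_onsets,
      duration = ph$duration,
      trial_type = ph$phase,
      trial = k,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write BIDS-style events.tsv files
#'
#' Tab-separated, onsets written with millisecond precision. The reader
#' returns the same column types the writer received, so a write/read
#' round trip is lossless at that precision.
#'
#' @param events data.frame as produced by [events_table()].
#' @param path file path.
#' @return `read_events_tsv` returns the events data.frame.
#' @export
write_events_tsv <- function(events, path) {
  ev <- events
  ev$onset <- sprintf("%.3f", ev$onset)
  ev$duration <- sprintf("%.3f", ev$duration)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  ev
}

#' Phase boundaries within a trial
#'
#' The analysis distinguishes early and late sub-phases of synchronization
#' and continuation. Two conventions coexist and are carried explicitly:
#' the behavioural analysis window ends at 26 s (late continuation spans
#' [7.5, 26) s), whereas the late-continuation fMRI regressor extends to
#' 26.5 s and the remaining trial time is covered by the stop/listen and
#' rest regressors. All intervals are half-open `[start, end)` so every
#' instant maps to exactly one phase.
#'
#' @param mode `"behavior"` or `"regressor"`.
#' @return data.frame with columns `phase`, `start`, `end` (seconds from
#'   the trial's synchronization onset).
#' @export
#' @examples
#' phase_boundaries("behavior")
phase_boundaries <- function(mode = c("behavior", "regressor")) {
  mode <- match.arg(mode)
  if (mode == "behavior") {
    data.frame(
      phase = c("sync1", "sync2", "cont1", "cont2"),
      start = c(0, 2.5, 6, 7.5),
      end = c(2.5, 6, 7.5, 26),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      phase = c("sync1", "sync2", "cont1", "cont2", "stop_listen", "rest"),
      start = c(0, 2.5, 6, 7.5, 26.5, 34),
      end = c(2.5, 6, 7.5, 26.5, 34, 54),
      stringsAsFactors = FALSE
    )
  }
}

#' Map a within-trial time to its phase
#'
#' @param t numeric vector of times in seconds relative to the trial's
#'   synchronization onset; must lie in `[0, 54)`.
#' @param mode boundary convention, see [phase_boundaries()].
#' @param boundaries optionally a custom boundary table.
#' @return character vector of phase labels. Under the behavioural
#'   convention, times at or beyond 26 s fall outside the analysed period
#'   and map to `NA`.
#' @export
#' @examples
#' phase_of(c(0, 7.0))          # "sync1" "cont1"
#' phase_of(26.2, "regressor")  # "cont2"
#' phase_of(26.2, "behavior")   # NA: outside the analysed 26-s period
phase_of <- function(t, mode = c("behavior", "regressor"),
                     boundaries = NULL) {
  mode <- match.arg(mode)
  if (is.null(boundaries)) boundaries <- phase_boundaries(mode)
  if (any(t < 0 | t >= 54)) {
    stop("within-trial times must lie in [0, 54)", call. = FALSE)
  }
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(boundaries))) {
    hit <- t >= boundaries$start[i] & t < boundaries$end[i]
    out[hit] <- boundaries$phase[i]
  }
  out
}

#' Condition (synchronization vs continuation) of a within-trial time
#'
#' Synchronization covers `[0, 6)` s, continuation `[6, 26)` s of the
#' behavioural analysis period; later times return `NA`.
#'
#' @param t numeric vector of within-trial times in seconds.
#' @return character vector with values `"sync"`, `"cont"` or `NA`.
#' @export
condition_of <- function(t) {
  out <- rep(NA_character_, length(t))
  out[t >= 0 & t < 6] <- "sync"
  out[t >= 6 & t < 26] <- "cont"
  out
}
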