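#' Ground-truth interval series of a tap record
#'
#' Applies the same inclusion rules as the detection pipeline (first tap
#' of each trial dropped, weak taps excluded, intervals outside the
#' validity bounds flagged) directly to the simulator's intended tap
#' times. Useful as the detector's reference and as a fast path when the
#' force rendering step is not under study.
#'
#' @param taps a `tap_record`.
#' @param bounds valid interval range, ms.
#' @return ITI `measurement_series` as from [compute_iti()].
#' @export
record_iti <- function(taps, bounds = c(250, 1000)) {
  rows <- lapply(sort(unique(taps$trial)), function(k) {
    all_tt <- taps[taps$trial == k, , drop = FALSE]
    all_tt <- all_tt[order(all_tt$onset), , drop = FALSE]
    first_weak <- nrow(all_tt) > 0 && all_tt$label[1] == "weak"
    tt <- all_tt[all_tt$label != "weak", , drop = FALSE]
    if (nrow(tt) < 3) return(NULL)
    # the reaction exclusion hits the trial-initial tap; when that tap
    # was already excluded as weak there is nothing further to drop
    if (!first_weak) tt <- tt[-1, , drop = FALSE]
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

#' Behavioural analysis of a simulated cohort
#'
#' Runs the per-run pipeline for every subject: high-pass filtering, tap
#' detection, interval/force measurement and exclusion accounting (or the
#' ground-truth fast path when traces were not rendered), then aggregates
#' cells across the cohort.
#'
#' @param cohort a `tap_cohort` from [make_cohort()].
#' @param use_traces detect taps from the rendered force traces (the full
#'   pipeline); if `FALSE`, or for subjects without traces, intervals come
#'   from the ground-truth record via [record_iti()].
#' @param ... passed to [detect_run()].
#' @return list with `cells` (see [aggregate_cells()]), `iti`
#'   (pooled series with `subject`/`run` columns), `summary`
#'   ([group_phase_summary()]), and `exclusions` (summed counts).
#' @export
analyze_cohort_behavior <- function(cohort, use_traces = TRUE, ...) {
  excl <- NULL
  iti_all <- vector("list", length(cohort))
  force_all <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    for (r in seq_along(subj$runs)) {
      run <- subj$runs[[r]]
      if (use_traces && !is.null(run$trace)) {
        res <- detect_run(run$trace, run$timeline, ...)
        iti <- res$iti
        force <- res$force
        excl <- if (is.null(excl)) res$exclusions else
          excl + res$exclusions
      } else {
        iti <- record_iti(run$taps)
        force <- NULL
      }
      if (nrow(iti)) {
        iti$subject <- subj$id
        iti$run <- r
        iti_all[[length(iti_all) + 1L]] <- iti
      }
      if (!is.null(force) && nrow(force)) {
        force$subject <- subj$id
        force$run <- r
        force_all[[length(force_all) + 1L]] <- force
      }
    }
  }
  iti <- do.call(rbind, iti_all)
  attr(iti, "kind") <- "iti"
  force <- if (length(force_all)) do.call(rbind, force_all) else NULL
  if (!is.null(force)) attr(force, "kind") <- "force"
  cells <- aggregate_cells(iti, force)
  list(cells = cells, iti = iti, force = force,
       summary = group_phase_summary(cells), exclusions = excl)
}
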