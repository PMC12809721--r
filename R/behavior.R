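#' Sliding-window moving-average parameters
#'
#' The SMA summarises a time-stamped tapping measure by its mean within a
#' window of half-width `half_width` centred on a grid of offset times.
#' The default window is 2 s wide (4-5 taps at a 500-ms period) and the
#' grid runs from 1 to 26 s in 0.5-s steps across the combined
#' synchronization-continuation period; window membership is closed on
#' both sides (`|t - centre| <= W`).
#'
#' @param half_width window half-width W, s.
#' @param grid_step grid increment, s.
#' @param period analysed period T, s.
#' @param grid window-centre times; defaults to `seq(1, period,
#'   grid_step)`.
#' @return list of class `sma_params`.
#' @export
sma_params <- function(half_width = 1, grid_step = 0.5, period = 26,
                       grid = NULL) {
  if (half_width <= 0) stop("half_width must be positive", call. = FALSE)
  if (is.null(grid)) grid <- seq(1, period, by = grid_step)
  if (any(grid < 0 | grid > period)) {
    stop("grid centres must lie within [0, period]", call. = FALSE)
  }
  structure(list(half_width = half_width, grid_step = grid_step,
                 period = period, grid = grid), class = "sma_params")
}

#' Sliding-window moving average of a measurement series
#'
#' Only valid samples enter the windows. Empty windows yield `NA` with a
#' count of zero. When the series spans several trials the trial-relative
#' timestamps are pooled, i.e. the curve is the trial-averaged time course.
#'
#' @param series a `measurement_series` (see [compute_iti()]).
#' @param params an [sma_params()].
#' @return data.frame of class `sma_series` with columns `center`, `mean`
#'   and `n`.
#' @export
sma <- function(series, params = sma_params()) {
  v <- series[series$valid & !is.na(series$value), , drop = FALSE]
  W <- params$half_width
  res <- vapply(params$grid, function(cen) {
    inw <- abs(v$time - cen) <= W
    n <- sum(inw)
    c(if (n) mean(v$value[inw]) else NA_real_, n)
  }, numeric(2))
  out <- data.frame(center = params$grid, mean = res[1, ], n = res[2, ])
  attr(out, "kind") <- attr(series, "kind")
  attr(out, "params") <- params
  class(out) <- c("sma_series", class(out))
  out
}

#' Tap-index-aligned values of a measurement series
#'
#' Orders the valid samples of every trial and averages across trials at
#' each tap index, producing a per-subject curve for event-based
#' averaging.
#'
#' @param series a `measurement_series`.
#' @return data.frame with columns `index` and `value` (trial-averaged).
#' @export
tap_indexed <- function(series) {
  v <- series[series$valid & !is.na(series$value), , drop = FALSE]
  rows <- lapply(unique(v$trial), function(k) {
    tt <- v[v$trial == k, , drop = FALSE]
    tt <- tt[order(tt$time), , drop = FALSE]
    data.frame(index = seq_len(nrow(tt)), value = tt$value)
  })
  d <- do.call(rbind, rows)
  out <- stats::aggregate(value ~ index, data = d, FUN = mean)
  out[order(out$index), ]
}

#' Event-based (n-th tap) group averaging
#'
#' The conventional alternative to the sliding-window average: the n-th
#' value of each subject is aligned with the `n * tone_period` time point
#' and averaged across subjects.
#'
#' @param curves data.frame with columns `subject`, `index`, `value`
#'   (per-subject tap-indexed curves, see [tap_indexed()]).
#' @param tone_period nominal inter-onset interval, ms.
#' @return data.frame with `index`, `time` (s), `mean`, `sd`, `n`.
#' @export
event_based_average <- function(curves, tone_period = 500) {
  sp <- split(curves$value, curves$index)
  idx <- as.integer(names(sp))
  out <- data.frame(
    index = idx,
    time = idx * tone_period / 1000,
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, stats::sd, numeric(1)),
    n = lengths(sp)
  )
  rownames(out) <- NULL
  out[order(out$index), ]
}

phase_to_stage <- function(phase) {
  c(sync1 = "early", sync2 = "late", cont1 = "early",
    cont2 = "late")[phase]
}

#' Per-cell behavioural summaries
#'
#' Aggregates valid samples into subject x condition x phase x run x
#' trial cells. Condition is synchronization for timestamps in [0, 6) s
#' and continuation for [6, 26) s; within each condition the early/late
#' phase split follows the behavioural phase boundaries. Phase `"all"`
#' rows summarise the whole condition. The coefficient of variation is
#' SD/mean within the cell.
#'
#' @param iti ITI `measurement_series` with additional `subject` and
#'   `run` columns.
#' @param force optional matching force series.
#' @param min_valid minimum valid ITI count for a cell to be reported.
#' @return data.frame with columns `subject`, `run`, `trial`,
#'   `condition`, `phase`, `mean_iti`, `cv_iti`, `n_valid` and, when
#'   `force` is given, `mean_force`, `cv_force`.
#' @export
aggregate_cells <- function(iti, force = NULL, min_valid = 1) {
  summarise_one <- function(s, prefix) {
    v <- s[s$valid & !is.na(s$value), , drop = FALSE]
    v$condition <- condition_of(v$time)
    v$phase <- phase_to_stage(phase_of(v$time, "behavior"))
    v <- v[!is.na(v$condition), , drop = FALSE]
    all_rows <- v
    all_rows$phase <- "all"
    v <- rbind(v, all_rows)
    key <- interaction(v$subject, v$run, v$trial, v$condition, v$phase,
                       drop = TRUE)
    sp <- split(v$value, key)
    meta <- v[!duplicated(key), c("subject", "run", "trial", "condition",
                                  "phase")]
    meta <- meta[order(unique(key)), ]
    m <- vapply(sp, mean, numeric(1))
    s_ <- vapply(sp, stats::sd, numeric(1))
    out <- cbind(meta, setNames(data.frame(m, s_ / m, lengths(sp)),
                                paste0(c("mean_", "cv_", "n_"), prefix)))
    rownames(out) <- NULL
    out
  }
  out <- summarise_one(iti, "iti")
  names(out)[names(out) == "n_iti"] <- "n_valid"
  out <- out[out$n_valid >= min_valid, , drop = FALSE]
  if (!is.null(force)) {
    f <- summarise_one(force, "force")
    f$n_force <- NULL
    out <- merge(out, f, by = c("subject", "run", "trial", "condition",
                                "phase"), all.x = TRUE)
  }
  out <- out[order(out$subject, out$run, out$trial, out$condition,
                   out$phase), ]
  rownames(out) <- NULL
  out
}

#' Group-level condition and phase means
#'
#' Collapses a cell table to subject means (unweighted over available
#' cells) and then to group mean and between-subject SD, for the two
#' conditions and the four behavioural phases.
#'
#' @param cells output of [aggregate_cells()].
#' @return data.frame with columns `level` (`sync`, `cont`, `sync1`,
#'   `sync2`, `cont1`, `cont2`), `mean_iti`, `sd_iti`, `mean_cv`,
#'   `sd_cv`, `n_subjects`.
#' @export
group_phase_summary <- function(cells) {
  lvl_def <- list(
    sync = c("sync", "all"), cont = c("cont", "all"),
    sync1 = c("sync", "early"), sync2 = c("sync", "late"),
    cont1 = c("cont", "early"), cont2 = c("cont", "late"))
  rows <- lapply(names(lvl_def), function(lv) {
    sel <- cells[cells$condition == lvl_def[[lv]][1] &
                   cells$phase == lvl_def[[lv]][2], , drop = FALSE]
    subj_iti <- tapply(sel$mean_iti, sel$subject, mean)
    subj_cv <- tapply(sel$cv_iti, sel$subject, mean, na.rm = TRUE)
    data.frame(level = lv,
               mean_iti = mean(subj_iti, na.rm = TRUE),
               sd_iti = stats::sd(subj_iti, na.rm = TRUE),
               mean_cv = mean(subj_cv, na.rm = TRUE),
               sd_cv = stats::sd(subj_cv, na.rm = TRUE),
               n_subjects = sum(!is.na(subj_iti)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress subject covariates out of cell metrics
#'
#' Replaces each metric by its residual from a least-squares fit on the
#' subjects' covariates, plus the grand mean, so downstream ANOVAs compare
#' covariate-adjusted values on the original scale.
#'
#' @param cells cell table with a `subject` column.
#' @param covariates data.frame with `subject` plus covariate columns.
#' @param metrics metric columns to adjust.
#' @param covars covariate names used in the fit.
#' @return the adjusted cell table.
#' @export
residualize_covariates <- function(cells, covariates,
                                   metrics = c("mean_iti", "cv_iti"),
                                   covars = c("age", "sex")) {
  if (!all(cells$subject %in% covariates$subject)) {
    stop("covariates missing for some subjects", call. = FALSE)
  }
  cov <- covariates[match(cells$subject, covariates$subject), covars,
                    drop = FALSE]
  for (cc in names(cov)) {
    if (length(unique(cov[[cc]])) < 2) {
      stop("covariate design is rank deficient: '", cc,
           "' is constant", call. = FALSE)
    }
  }
  X <- stats::model.matrix(~ ., data = cov)
  if (qr(X)$rank < ncol(X)) {
    stop("covariate design is rank deficient (constant or collinear ",
         "columns)", call. = FALSE)
  }
  for (m in intersect(metrics, names(cells))) {
    y <- cells[[m]]
    ok <- !is.na(y)
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    cells[[m]][ok] <- fit$residuals + mean(y[ok])
  }
  cells
}

#' Repeated-measures ANOVA on a cell table
#'
#' Cells are first averaged to one value per subject and factor
#' combination (unweighted means over available runs/trials); subjects
#' missing any combination are dropped for the test and reported. The
#' model is a classical within-subject ANOVA, `dv ~ f1 * f2 * ... +
#' Error(subject/(f1 * f2 * ...))`, so every effect is tested against its
#' own subject-by-effect error stratum. Pairwise post-hoc comparisons of
#' the marginal means use the Tukey-Kramer studentized-range criterion on
#' the matching stratum.
#'
#' @param cells cell table (see [aggregate_cells()]).
#' @param dv dependent-variable column.
#' @param factors within-subject factor columns (each with >= 2 observed
#'   levels).
#' @param subject subject identifier column.
#' @return object of class `rm_anova`: list with `table` (effect, df1,
#'   df2, F, p), `posthoc` (per-factor Tukey-Kramer tables),
#'   `n_subjects`, `dropped`.
#' @export
rm_anova <- function(cells, dv = "mean_iti",
                     factors = c("condition", "run", "trial"),
                     subject = "subject") {
  d <- cells[, c(subject, factors, dv)]
  names(d) <- c("subject", factors, "value")
  d <- d[!is.na(d$value), , drop = FALSE]
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  d$subject <- factor(d$subject)
  agg <- stats::aggregate(value ~ ., data = d, FUN = mean)

  n_cells <- prod(vapply(factors, function(f) nlevels(d[[f]]), integer(1)))
  cnt <- table(agg$subject)
  complete <- names(cnt)[cnt == n_cells]
  dropped <- setdiff(levels(d$subject), complete)
  agg <- agg[agg$subject %in% complete, , drop = FALSE]
  agg$subject <- droplevels(agg$subject)
  if (nlevels(agg$subject) < 2) {
    stop("fewer than 2 subjects with complete cells", call. = FALSE)
  }

  fx <- paste(factors, collapse = " * ")
  form <- stats::as.formula(sprintf(
    "value ~ %s + Error(subject/(%s))", fx, fx))
  fit <- stats::aov(form, data = agg)
  sm <- summary(fit)

  tab <- list()
  strata <- list()
  for (snm in names(sm)) {
    s <- sm[[snm]][[1]]
    rn <- trimws(rownames(s))
    res <- rn == "Residuals"
    if (!any(res)) next
    mse <- s[res, "Mean Sq"]
    dfe <- s[res, "Df"]
    strata[[sub("^Error: ", "", snm)]] <- list(mse = mse, df = dfe)
    eff <- which(!res)
    if (length(eff)) {
      tab[[snm]] <- data.frame(effect = rn[eff], df1 = s[eff, "Df"],
                               df2 = dfe, F = s[eff, "F value"],
                               p = s[eff, "Pr(>F)"])
    }
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL

  posthoc <- lapply(factors, function(f) {
    stratum <- strata[[paste0("subject:", f)]]
    if (is.null(stratum) || stratum$df < 2 ||
        !is.finite(stratum$mse)) return(NULL)
    m <- tapply(agg$value, agg[[f]], mean)
    nsub <- nlevels(agg$subject)
    b <- n_cells / nlevels(agg[[f]])  # cells averaged per subject-level
    lv <- names(m)
    pairs <- utils::combn(lv, 2)
    se <- sqrt(stratum$mse / (nsub * b))
    q <- abs(m[pairs[1, ]] - m[pairs[2, ]]) / se
    data.frame(level1 = pairs[1, ], level2 = pairs[2, ],
               diff = unname(m[pairs[1, ]] - m[pairs[2, ]]),
               q = unname(q),
               p_adj = stats::ptukey(unname(q), length(lv), stratum$df,
                                     lower.tail = FALSE),
               row.names = NULL)
  })
  names(posthoc) <- factors

  structure(list(table = tab, posthoc = posthoc,
                 n_subjects = nlevels(agg$subject), dropped = dropped),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA (%d subjects", x$n_subjects))
  if (length(x$dropped)) {
    cat(sprintf(", %d dropped for incomplete cells", length(x$dropped)))
  }
  cat(")\n")
  print(x$table, digits = 4)
  invisible(x)
}
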