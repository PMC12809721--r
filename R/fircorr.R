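#' Finite-impulse-response design for the tapping period
#'
#' Models the 26-s synchronization-continuation window of every trial
#' with 26 one-second bin regressors time-locked to the trial's
#' synchronization onset: each task volume inside a trial's window loads
#' exactly one bin. The listen period (7.5 s, covering stop + listen) and
#' rest (20 s) are modelled as boxcar nuisance regressors, and a
#' discrete-cosine high-pass basis plus intercept complete the matrix.
#'
#' @param timeline a [run_timeline()].
#' @param n_bins number of FIR bins.
#' @param bin_width bin width, seconds.
#' @param highpass high-pass cutoff, seconds.
#' @return an `fmri_design` whose `fir_cols` name the bin columns.
#' @export
build_fir_design <- function(timeline, n_bins = 26, bin_width = 1,
                             highpass = 90) {
  stopifnot(inherits(timeline, "run_timeline"))
  nv <- timeline$n_volumes
  vol_t <- (seq_len(nv) - 1) * timeline$tr
  fir <- matrix(0, nv, n_bins,
                dimnames = list(NULL, paste0("fir", seq_len(n_bins))))
  listen <- numeric(nv)
  rest <- numeric(nv)
  for (on in timeline$trial_onsets) {
    u <- vol_t - on
    inwin <- u >= 0 & u < n_bins * bin_width
    b <- floor(u[inwin] / bin_width) + 1
    fir[cbind(which(inwin), b)] <- 1
    listen[u >= 26.5 & u < 34] <- 1
    rest[u >= 34 & u < 54] <- 1
  }
  rows <- which(vol_t >= timeline$task_block_start &
                  vol_t < timeline$task_block_start +
                    timeline$task_block_duration)
  hpb <- dct_basis(length(rows), timeline$tr, highpass)
  hp <- matrix(0, nv, ncol(hpb), dimnames = list(NULL, colnames(hpb)))
  if (ncol(hpb)) hp[rows, ] <- hpb
  X <- cbind(fir, listen = listen, rest = rest, hp, intercept = 1)
  structure(list(X = X, task_cols = colnames(fir),
                 fir_cols = colnames(fir), rows = rows,
                 tr = timeline$tr, timeline = timeline,
                 bin_width = bin_width,
                 nuisance_durations = c(listen = 7.5, rest = 20)),
            class = "fmri_design")
}

#' Fit the FIR model and extract per-voxel response courses
#'
#' Least squares as in [fit_glm()]; returns the matrix of FIR bin
#' estimates, one unconstrained response amplitude per post-onset second.
#'
#' @param vol a `volume_series`.
#' @param design a [build_fir_design()] design.
#' @param prewhiten apply AR(1) prewhitening.
#' @return list with `betas` (n_bins x V matrix), `times` (bin onsets,
#'   s), `grid`, and the full `fit`.
#' @export
fit_fir <- function(vol, design, prewhiten = FALSE) {
  fit <- fit_glm(vol, design, prewhiten = prewhiten)
  bi <- match(design$fir_cols, fit$columns)
  betas <- fit$beta[bi, , drop = FALSE]
  list(betas = betas,
       times = (seq_along(design$fir_cols) - 1) * design$bin_width,
       grid = fit$grid, fit = fit)
}

#' Linearly upsample FIR courses to a finer grid
#'
#' @param betas numeric vector (one course) or matrix (bins x V).
#' @param times bin times, seconds.
#' @param to_step target sampling step, seconds.
#' @return list with `betas` (upsampled matrix) and `times`; endpoints
#'   are preserved, midpoints equal bin-pair means.
#' @export
upsample_betas <- function(betas, times = NULL, to_step = 0.5) {
  if (is.vector(betas)) betas <- matrix(betas, ncol = 1)
  if (is.null(times)) times <- seq_len(nrow(betas)) - 1
  tout <- seq(times[1], times[length(times)], by = to_step)
  out <- apply(betas, 2, function(v) {
    stats::approx(times, v, xout = tout)$y
  })
  list(betas = matrix(out, nrow = length(tout)), times = tout)
}

#' Behavioural deviation series on the SMA grid
#'
#' Converts a sliding-window curve into the deviation measure used for
#' brain-behaviour coupling: for interval measures, the absolute
#' deviation from the 500-ms target; for force, the absolute z score
#' (within the series). Larger values always mean worse tapping.
#'
#' @param sma_series an `sma_series` (see [sma()]).
#' @param target target interval, ms (interval kinds only).
#' @param kind `"iti"` or `"force"`; defaults to the series' own kind.
#' @return data.frame with `center` (s) and `value`; `NA` where the
#'   window was empty.
#' @export
behavior_deviation <- function(sma_series, target = 500, kind = NULL) {
  if (is.null(kind)) kind <- attr(sma_series, "kind")
  v <- sma_series$mean
  val <- if (identical(kind, "force")) {
    abs((v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE))
  } else {
    abs(v - target)
  }
  data.frame(center = sma_series$center, value = val)
}

#' Lagged correlation between behaviour and FIR response courses
#'
#' Pearson correlation between the behavioural deviation at time `t` and
#' the (upsampled) response estimate at `t + lag`, for haemodynamic lags
#' of 0-6 s, computed over the overlapping support; missing behavioural
#' points are excluded pairwise.
#'
#' @param beta_up upsampled courses: list from [upsample_betas()].
#' @param behavior deviation series from [behavior_deviation()].
#' @param lags haemodynamic delays, seconds.
#' @param min_overlap minimum number of paired points per lag.
#' @return matrix `length(lags)` x V of correlations (rownames are the
#'   lags); `NA` where the overlap is insufficient.
#' @export
lagged_correlation <- function(beta_up, behavior, lags = 0:6,
                               min_overlap = 10) {
  bt <- beta_up$times
  step <- bt[2] - bt[1]
  out <- matrix(NA_real_, length(lags), ncol(beta_up$betas),
                dimnames = list(lags, NULL))
  for (i in seq_along(lags)) {
    tgt <- behavior$center + lags[i]
    idx <- round((tgt - bt[1]) / step) + 1
    ok <- !is.na(behavior$value) & idx >= 1 & idx <= length(bt) &
      abs(tgt - bt[pmax(1, pmin(length(bt), idx))]) < step / 4
    if (sum(ok) < min_overlap) next
    out[i, ] <- suppressWarnings(
      stats::cor(behavior$value[ok], beta_up$betas[idx[ok], , drop = FALSE]))
  }
  out
}

#' Run-averaged lag-correlation map for one subject
#'
#' @param run_maps list of per-run lag x V correlation matrices.
#' @return element-wise mean across runs (NAs removed pairwise).
#' @export
average_run_maps <- function(run_maps) {
  arr <- array(unlist(run_maps),
               dim = c(dim(run_maps[[1]]), length(run_maps)))
  apply(arr, c(1, 2), mean, na.rm = TRUE)
}

#' Group permutation inference on lag-correlation maps
#'
#' Subject maps are Fisher-z transformed, covariates are regressed out,
#' and a one-sample sign-flip permutation test is run per voxel and lag.
#' Family-wise error across all voxels (and, by default, lags) is
#' controlled with the maximum-|t| statistic; voxels whose |t| exceeds
#' the permutation null's 95th percentile of the maximum are significant,
#' with the effect sign distinguishing positive from negative coupling.
#'
#' @param maps list (one per subject) of lag x V correlation matrices,
#'   run-averaged (see [average_run_maps()]).
#' @param covariates optional data.frame of subject covariates (e.g.
#'   age, sex, framewise displacement).
#' @param n_perm number of sign flips; fewer than 100 triggers a
#'   warning.
#' @param seed RNG seed.
#' @param alpha family-wise error level.
#' @param across_lags correct across lags jointly (otherwise per lag).
#' @return list with `t` (lag x V), `df`, `p_fwe` (lag x V), `sig_pos`,
#'   `sig_neg` (logical lag x V), `threshold`.
#' @export
group_permutation <- function(maps, covariates = NULL, n_perm = 1000,
                              seed = 1, alpha = 0.05,
                              across_lags = TRUE) {
  if (n_perm < 100) {
    warning("fewer than 100 permutations gives a coarse null",
            call. = FALSE)
  }
  n <- length(maps)
  if (n < 8) stop("group inference needs at least 8 subjects",
                  call. = FALSE)
  dims <- dim(maps[[1]])
  Y <- t(vapply(maps, function(m) {
    as.vector(atanh(pmax(pmin(m, 0.999), -0.999)))
  }, numeric(prod(dims))))
  keep <- colSums(is.na(Y)) == 0
  rz <- residualize_matrix(Y[, keep, drop = FALSE], covariates)
  df <- n - 1 - rz$q

  tobs <- rep(NA_real_, prod(dims))
  tobs[keep] <- perm_tmat(matrix(1, 1, n), rz$Y)[1, ]

  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Tp <- abs(perm_tmat(S, rz$Y))

  lag_of <- rep(seq_len(dims[1]), times = dims[2])[keep]
  tm <- matrix(tobs, dims[1], dims[2], dimnames = dimnames(maps[[1]]))
  p_fwe <- matrix(NA_real_, dims[1], dims[2])
  thr <- numeric(dims[1])
  if (across_lags) {
    null_max <- apply(Tp, 1, max)
    thr[] <- stats::quantile(null_max, 1 - alpha, names = FALSE)
    p_fwe[keep] <- vapply(abs(tobs[keep]), function(tt) {
      (1 + sum(null_max >= tt)) / (1 + n_perm)
    }, numeric(1))
  } else {
    for (l in seq_len(dims[1])) {
      cols <- which(lag_of == l)
      if (!length(cols)) next
      null_max <- apply(Tp[, cols, drop = FALSE], 1, max)
      thr[l] <- stats::quantile(null_max, 1 - alpha, names = FALSE)
      idx_full <- which(keep)[cols]
      p_fwe[idx_full] <- vapply(abs(tobs[idx_full]), function(tt) {
        (1 + sum(null_max >= tt)) / (1 + n_perm)
      }, numeric(1))
    }
  }
  sig <- !is.na(p_fwe) & p_fwe < alpha
  list(t = tm, df = df, p_fwe = p_fwe,
       sig_pos = sig & tm > 0, sig_neg = sig & tm < 0,
       threshold = thr)
}

#' Volume-sampled coupling regressor from a behavioural series
#'
#' Maps a within-trial behavioural deviation curve onto the run's volume
#' grid, shifted by a haemodynamic delay: volume at run time `t` takes
#' the behaviour value at within-trial time `t - onset - delay` (linear
#' interpolation, zero outside the 26-s tapping window). Used to plant
#' behaviour-coupled BOLD signal in simulations and to reason about what
#' the lag-correlation analysis should recover.
#'
#' @param timeline a [run_timeline()].
#' @param behavior deviation series (see [behavior_deviation()]).
#' @param delay haemodynamic delay, seconds.
#' @return numeric vector of length `n_volumes`.
#' @export
coupling_regressor <- function(timeline, behavior, delay = 4) {
  vol_t <- (seq_len(timeline$n_volumes) - 1) * timeline$tr
  out <- numeric(timeline$n_volumes)
  b <- behavior[!is.na(behavior$value), ]
  if (!nrow(b)) return(out)
  for (on in timeline$trial_onsets) {
    u <- vol_t - on - delay
    inw <- u >= 0 & u < 26
    out[inw] <- stats::approx(b$center, b$value, xout = u[inw],
                              rule = 2)$y
  }
  out
}
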