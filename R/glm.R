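#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the canonical 6-s response
#' peak, 16-s undershoot peak and 1:6 undershoot ratio, normalised to a
#' peak of 1.
#'
#' @param t time since event, seconds (vector).
#' @param peak_delay,undershoot_delay gamma shape parameters (scale 1),
#'   i.e. response and undershoot peak delays in seconds.
#' @param ratio response/undershoot amplitude ratio.
#' @return numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6) {
  raw <- function(x) {
    stats::dgamma(x, shape = peak_delay, scale = 1) -
      stats::dgamma(x, shape = undershoot_delay, scale = 1) / ratio
  }
  h <- raw(t)
  h[t < 0] <- 0
  h / max(raw(seq(0, 32, by = 0.01)))
}

# boxcar on a fine time grid for one phase interval across all trials
phase_boxcar <- function(grid, timeline, start, end) {
  box <- numeric(length(grid))
  for (on in timeline$trial_onsets) {
    box[grid >= on + start & grid < on + end] <- 1
  }
  box
}

#' Block design matrix for the six-phase GLM
#'
#' Builds HRF-convolved boxcar regressors for early/late synchronization,
#' early/late continuation, the combined stop/listen period and rest,
#' using the regressor-mode phase boundaries (late continuation extends
#' to 26.5 s). Temporal derivatives of the task regressors, a
#' discrete-cosine high-pass basis (cutoff `highpass` seconds, computed
#' over the task block), optional volume-wise confounds and an intercept
#' complete the matrix. Estimation is restricted to the task-block
#' volumes (`rows`), matching the convention of fitting the first level
#' to the 324 task volumes.
#'
#' @param timeline a [run_timeline()].
#' @param highpass high-pass cutoff, seconds; a warning is issued when it
#'   is shorter than the longest modelled block.
#' @param confounds optional numeric matrix/data.frame with `n_volumes`
#'   rows (e.g. volume-wise framewise displacement).
#' @param derivatives include temporal derivatives of the task
#'   regressors.
#' @param hrf function of time returning the impulse response.
#' @param dt microtime resolution for convolution, seconds.
#' @return object of class `fmri_design`: list with `X` (n_volumes x p),
#'   `task_cols`, `rows` (task-block volume indices), `tr`.
#' @export
build_design <- function(timeline, highpass = 90, confounds = NULL,
                         derivatives = TRUE, hrf = hrf_double_gamma,
                         dt = 0.1) {
  stopifnot(inherits(timeline, "run_timeline"))
  pb <- phase_boundaries("regressor")
  labels <- c(sync1 = "Sync1", sync2 = "Sync2", cont1 = "Cont1",
              cont2 = "Cont2", stop_listen = "StopListen", rest = "Rest")
  if (highpass < max(pb$end - pb$start)) {
    warning("high-pass cutoff shorter than the longest block; task ",
            "variance will be attenuated", call. = FALSE)
  }

  grid <- seq(0, timeline$run_duration, by = dt)
  h <- hrf(seq(0, 32, by = dt))
  vol_t <- (seq_len(timeline$n_volumes) - 1) * timeline$tr

  task <- sapply(seq_len(nrow(pb)), function(i) {
    box <- phase_boxcar(grid, timeline, pb$start[i], pb$end[i])
    if (all(box == 0)) {
      stop("phase '", pb$phase[i], "' produces an all-zero regressor",
           call. = FALSE)
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] *
      dt
    stats::approx(grid, conv, xout = vol_t, rule = 2)$y
  })
  colnames(task) <- labels[pb$phase]

  X <- task
  if (derivatives) {
    d <- apply(task, 2, function(v) c(0, diff(v)))
    colnames(d) <- paste0(colnames(task), "_deriv")
    X <- cbind(X, d)
  }
  rows <- which(vol_t >= timeline$task_block_start &
                  vol_t < timeline$task_block_start +
                    timeline$task_block_duration)
  hp <- matrix(0, nrow = timeline$n_volumes, ncol = 0)
  hpb <- dct_basis(length(rows), timeline$tr, highpass)
  if (ncol(hpb)) {
    hp <- matrix(0, nrow = timeline$n_volumes, ncol = ncol(hpb),
                 dimnames = list(NULL, colnames(hpb)))
    hp[rows, ] <- hpb
  }
  X <- cbind(X, hp)
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    if (nrow(cf) != timeline$n_volumes) {
      stop("confounds must have one row per volume", call. = FALSE)
    }
    if (is.null(colnames(cf))) {
      colnames(cf) <- paste0("confound", seq_len(ncol(cf)))
    }
    X <- cbind(X, cf)
  }
  X <- cbind(X, intercept = 1)
  structure(list(X = X, task_cols = unname(labels[pb$phase]),
                 rows = rows, tr = timeline$tr, timeline = timeline),
            class = "fmri_design")
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares per voxel on the task-block volumes, with
#' optional AR(1) prewhitening: residual lag-one autocorrelation is
#' estimated per voxel, voxels are pooled into bins of similar
#' autocorrelation, and each bin is refit after Prais-Winsten
#' quasi-differencing (a two-pass Cochrane-Orcutt scheme).
#'
#' @param vol a `volume_series` (or 4D array).
#' @param design an `fmri_design` (from [build_design()] or
#'   [build_fir_design()]).
#' @param prewhiten apply the AR(1) correction.
#' @param rho_bin bin width for pooling autocorrelation estimates.
#' @return object of class `fmri_fit`: list with `beta` (p x V), `sigma2`
#'   (residual variance), `df`, `rho`, per-bin `(X'X)^-1`, the voxel grid
#'   and column names.
#' @export
fit_glm <- function(vol, design, prewhiten = TRUE, rho_bin = 0.05) {
  a <- if (inherits(vol, "volume_series")) vol$data else vol
  grid <- dim(a)[1:3]
  Y <- vol_matrix(a)
  if (nrow(Y) != nrow(design$X)) {
    stop("volume count does not match the design", call. = FALSE)
  }
  X <- design$X[design$rows, , drop = FALSE]
  Y <- Y[design$rows, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta

  if (!prewhiten) {
    sigma2 <- colSums(res^2) / (n - p)
    xtxinv <- chol2inv(qr.R(qrX))
    return(structure(list(beta = beta, sigma2 = sigma2, df = n - p,
                          rho = rep(0, ncol(Y)),
                          bins = list(list(rho = 0, xtxinv = xtxinv,
                                           voxels = seq_len(ncol(Y)))),
                          grid = grid, columns = colnames(X),
                          task_cols = design$task_cols),
                     class = "fmri_fit"))
  }

  rho <- colSums(res[-1, , drop = FALSE] * res[-n, , drop = FALSE]) /
    colSums(res^2)
  rho[!is.finite(rho)] <- 0
  rho <- pmax(pmin(rho, 0.95), -0.95)
  rho_b <- round(rho / rho_bin) * rho_bin

  sigma2 <- numeric(ncol(Y))
  bins <- list()
  for (rb in sort(unique(rho_b))) {
    vx <- which(rho_b == rb)
    w1 <- sqrt(1 - rb^2)
    Xs <- rbind(X[1, ] * w1, X[-1, ] - rb * X[-n, ])
    Ys <- rbind(Y[1, vx, drop = FALSE] * w1,
                Y[-1, vx, drop = FALSE] - rb * Y[-n, vx, drop = FALSE])
    qs <- qr(Xs)
    b <- qr.coef(qs, Ys)
    r <- Ys - Xs %*% b
    beta[, vx] <- b
    sigma2[vx] <- colSums(r^2) / (n - p)
    bins[[length(bins) + 1]] <- list(rho = rb,
                                     xtxinv = chol2inv(qr.R(qs)),
                                     voxels = vx)
  }
  structure(list(beta = beta, sigma2 = sigma2, df = n - p, rho = rho,
                 bins = bins, grid = grid, columns = colnames(X),
                 task_cols = design$task_cols),
            class = "fmri_fit")
}

#' Contrast of GLM parameter estimates
#'
#' Computes `effect = c'beta`, its variance and the Z-transformed t
#' statistic per voxel. Weights may be given as a named vector over task
#' columns (all other columns get weight zero) or as a full-length
#' vector.
#'
#' @param fit an `fmri_fit`.
#' @param weights contrast weights.
#' @param name contrast label.
#' @return object of class `stat_map`: list with 3D arrays `effect`,
#'   `var`, `z`, plus `df` and `name`.
#' @export
contrast_map <- function(fit, weights, name = NULL) {
  p <- length(fit$columns)
  cvec <- numeric(p)
  names(cvec) <- fit$columns
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), fit$columns)
    if (length(unknown)) {
      stop("unknown design columns: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cvec[names(weights)] <- weights
  } else {
    if (length(weights) != p) {
      stop("contrast length must match the design", call. = FALSE)
    }
    cvec[] <- weights
  }
  eff <- drop(crossprod(cvec, fit$beta))
  vfac <- numeric(length(eff))
  for (b in fit$bins) {
    vfac[b$voxels] <- drop(crossprod(cvec, b$xtxinv %*% cvec))
  }
  v <- fit$sigma2 * vfac
  t <- eff / sqrt(v)
  t[!is.finite(t)] <- 0
  structure(list(effect = array(eff, fit$grid), var = array(v, fit$grid),
                 z = array(zstat_from_t(t, fit$df), fit$grid),
                 df = fit$df,
                 name = if (is.null(name)) "contrast" else name),
            class = "stat_map")
}

#' Fixed-effects combination of per-run contrast maps
#'
#' Inverse-variance-weighted average of the run effects; the combined
#' variance is the reciprocal summed precision and Z is the combined
#' effect over its standard error.
#'
#' @param maps list of `stat_map`s with identical geometry.
#' @return combined `stat_map`.
#' @export
combine_runs_fixed_effects <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- dim(maps[[1]]$effect)
  for (m in maps) {
    if (!identical(dim(m$effect), dims)) {
      stop("stat maps have mismatched geometry", call. = FALSE)
    }
  }
  wsum <- array(0, dims); esum <- array(0, dims)
  for (m in maps) {
    w <- 1 / m$var
    wsum <- wsum + w
    esum <- esum + w * m$effect
  }
  eff <- esum / wsum
  v <- 1 / wsum
  structure(list(effect = eff, var = v, z = eff / sqrt(v), df = Inf,
                 name = maps[[1]]$name),
            class = "stat_map")
}

# vectorised one-sample t for sign-flip permutations:
# S is P x n of +-1, Y is n x V; returns P x V matrix of t statistics
perm_tmat <- function(S, Y) {
  n <- nrow(Y)
  m <- (S %*% Y) / n
  ss <- rep(colSums(Y^2), each = nrow(S))
  v <- (matrix(ss, nrow(S)) - n * m^2) / (n - 1)
  v[v <= 0] <- Inf
  m / sqrt(v / n)
}

#' Group-level statistics with permutation cluster inference
#'
#' One-sample test of the subject effect maps (optionally after
#' regressing out subject covariates), Z-transformed and thresholded at
#' `z_thresh`; cluster extents are assessed against the null
#' distribution of the maximum cluster size under sign-flip permutation,
#' giving family-wise-error-corrected cluster p values.
#'
#' @param maps 4D array (x, y, z, subject) of effect estimates, or a list
#'   of `stat_map`s whose effects are stacked.
#' @param covariates optional data.frame of subject covariates.
#' @param z_thresh cluster-forming threshold on |Z|.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed for the permutations.
#' @param alternative `"greater"` tests positive effects only;
#'   `"two.sided"` forms clusters in both tails.
#' @return list with `z` (3D array), `t`, `df`, `clusters` (data.frame:
#'   id, sign, size, peak coordinates, peak Z, p_fwe), `sig_mask`
#'   (logical 3D array of voxels in significant clusters at p < 0.05)
#'   and `null_max_size`.
#' @export
group_stats <- function(maps, covariates = NULL, z_thresh = 3.1,
                        n_perm = 1000, seed = 1,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.list(maps)) {
    dims <- dim(maps[[1]]$effect)
    arr <- array(unlist(lapply(maps, `[[`, "effect")),
                 dim = c(dims, length(maps)))
  } else {
    arr <- maps
    dims <- dim(arr)[1:3]
  }
  n <- dim(arr)[4]
  if (n < 8) stop("group inference needs at least 8 subjects",
                  call. = FALSE)
  Y <- t(matrix(arr, nrow = prod(dims)))
  rz <- residualize_matrix(Y, covariates)
  Y <- rz$Y
  df <- n - 1 - rz$q

  tobs <- perm_tmat(matrix(1, 1, n), Y)[1, ]
  zobs <- zstat_from_t(tobs, df)
  zarr <- array(zobs, dims)

  t_thr <- stats::qt(stats::pnorm(z_thresh, lower.tail = FALSE), df,
                     lower.tail = FALSE)

  obs_clusters <- function(tv) {
    out <- NULL
    signs <- if (alternative == "greater") 1 else c(1, -1)
    for (sg in signs) {
      lab <- label_clusters(array(sg * tv > t_thr, dims))
      if (max(lab) == 0) next
      for (k in seq_len(max(lab))) {
        vx <- which(lab == k)
        pk <- vx[which.max(sg * tv[vx])]
        co <- arrayInd(pk, dims)
        out <- rbind(out, data.frame(
          id = k, sign = sg, size = length(vx),
          x = co[1], y = co[2], z = co[3],
          peak_z = zstat_from_t(tv[pk], df), voxels = I(list(vx))))
      }
    }
    out
  }
  cl <- obs_clusters(tobs)

  max_size_of <- function(tv) {
    hot <- if (alternative == "greater") tv > t_thr else abs(tv) > t_thr
    if (!any(hot)) return(0L)
    if (sum(hot) == 1) return(1L)
    if (alternative == "greater") {
      max(cluster_sizes(label_clusters(array(hot, dims))))
    } else {
      mx <- 0L
      for (sg in c(1, -1)) {
        m <- array(sg * tv > t_thr, dims)
        if (any(m)) mx <- max(mx, cluster_sizes(label_clusters(m)))
      }
      mx
    }
  }

  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Tp <- perm_tmat(S, Y)
  null_max <- apply(Tp, 1, max_size_of)

  sig_mask <- array(FALSE, dims)
  if (!is.null(cl)) {
    cl$p_fwe <- vapply(cl$size, function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1))
    for (i in seq_len(nrow(cl))) {
      if (cl$p_fwe[i] < 0.05) sig_mask[cl$voxels[[i]]] <- TRUE
    }
    cl$voxels <- NULL
  } else {
    cl <- data.frame(id = integer(0), sign = numeric(0),
                     size = integer(0), x = integer(0), y = integer(0),
                     z = integer(0), peak_z = numeric(0),
                     p_fwe = numeric(0))
  }
  list(z = zarr, t = array(tobs, dims), df = df, clusters = cl,
       sig_mask = sig_mask, null_max_size = null_max,
       z_thresh = z_thresh)
}
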