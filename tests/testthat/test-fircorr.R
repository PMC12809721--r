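tl <- run_timeline()

test_that("the FIR design partitions the tapping window", {
  des <- build_fir_design(tl)
  expect_equal(length(des$fir_cols), 26L)
  expect_equal(unname(des$nuisance_durations["listen"]), 7.5)
  expect_equal(unname(des$nuisance_durations["rest"]), 20)
  # every volume inside a trial's 26-s window loads exactly one bin
  vol_t <- (seq_len(tl$n_volumes) - 1) * tl$tr
  u <- (vol_t - tl$task_block_start) %% 54
  intask <- seq_along(vol_t) %in% des$rows
  loads <- rowSums(des$X[, des$fir_cols])
  expect_true(all(loads[intask & u < 26] == 1))
  expect_true(all(loads[!intask | u >= 26.5] %in% 0))
  # each bin collects one volume per trial
  expect_equal(unname(colSums(des$X[, des$fir_cols])), rep(6, 26))
})

test_that("noiseless FIR recovery returns the planted profile", {
  des <- build_fir_design(tl)
  profile <- sin(seq(0, pi, length.out = 26))
  ts <- as.vector(des$X[, des$fir_cols] %*% profile)
  bp <- bold_params(grid = c(3, 3, 1), noise_sd = 0,
                    effects = list(list(mask = array(TRUE, c(3, 3, 1)),
                                        ts = ts, amplitude = 1)))
  ff <- fit_fir(simulate_bold(tl, bp), des)
  expect_equal(unname(ff$betas[, 1]), profile, tolerance = 1e-8)
})

test_that("an HRF-shaped response peaks at haemodynamic latency", {
  des <- build_fir_design(tl)
  # plant a response to each synchronization onset with canonical shape
  grid <- seq(0, tl$run_duration, by = 0.1)
  stick <- numeric(length(grid))
  stick[vapply(tl$trial_onsets, function(on) which.min(abs(grid - on)),
               integer(1))] <- 1
  h <- hrf_double_gamma(seq(0, 32, by = 0.1))
  conv <- stats::convolve(stick, rev(h), type = "open")[seq_along(grid)]
  ts <- approx(grid, conv, xout = (seq_len(tl$n_volumes) - 1))$y
  bp <- bold_params(grid = c(2, 2, 1), noise_sd = 0,
                    effects = list(list(mask = array(TRUE, c(2, 2, 1)),
                                        ts = ts, amplitude = 1)))
  ff <- fit_fir(simulate_bold(tl, bp), des)
  peak_bin <- ff$times[which.max(ff$betas[, 1])]
  expect_gte(peak_bin, 4)
  expect_lte(peak_bin, 6)
})

test_that("upsampling is exact linear interpolation", {
  ramp <- 2 * (0:25) + 1
  up <- upsample_betas(ramp)
  expect_equal(up$times, seq(0, 25, by = 0.5))
  expect_equal(up$betas[, 1], 2 * up$times + 1)

  set.seed(6)
  v <- rnorm(26)
  up2 <- upsample_betas(v)
  # endpoints preserved, midpoints are bin-pair means
  expect_equal(up2$betas[seq(1, 51, by = 2), 1], v)
  expect_equal(up2$betas[seq(2, 50, by = 2), 1],
               (v[-26] + v[-1]) / 2)
  # decimation round trip
  expect_equal(upsample_betas(up2$betas[, 1], up2$times,
                              to_step = 1)$betas[, 1], v)
})

test_that("behavioural deviation series measure distance from target", {
  s <- data.frame(center = seq(1, 26, 0.5),
                  mean = c(rep(490, 10), rep(510, 41)), n = 5)
  attr(s, "kind") <- "iti"
  class(s) <- c("sma_series", class(s))
  d <- behavior_deviation(s)
  expect_equal(d$value, c(rep(10, 10), rep(10, 41)))
  attr(s, "kind") <- "force"
  dz <- behavior_deviation(s)
  expect_true(all(dz$value >= 0))
})

test_that("lagged correlation finds a planted shift", {
  set.seed(10)
  base <- cumsum(rnorm(51))
  bt <- seq(0, 25, by = 0.5)
  # behaviour at t equals the course at t + 2: r(2) = 1
  beh <- data.frame(center = seq(1, 26, 0.5),
                    value = approx(bt, base, xout = seq(3, 28, 0.5),
                                   rule = 2)$y)
  up <- list(betas = matrix(base, ncol = 1), times = bt)
  r <- lagged_correlation(up, beh)
  expect_equal(unname(r["2", 1]), 1, tolerance = 1e-10)
  expect_true(all(r[c("0", "4", "6"), 1] < 1 - 1e-6))

  # independent noise decorrelates
  beh0 <- data.frame(center = seq(1, 26, 0.5), value = rnorm(51))
  r0 <- lagged_correlation(up, beh0)
  expect_true(all(abs(r0) < 0.9))
  expect_true(all(r >= -1 & r <= 1))
})

test_that("sign-flip inference is antisymmetric in the behaviour sign", {
  set.seed(21)
  n <- 10
  maps <- lapply(1:n, function(i) {
    matrix(rnorm(7 * 40, mean = rep(c(0.4, 0), c(10, 30))), 7, 40,
           byrow = TRUE)
  })
  g1 <- group_permutation(maps, n_perm = 400, seed = 5)
  g2 <- group_permutation(lapply(maps, function(m) -m), n_perm = 400,
                          seed = 5)
  expect_equal(g1$t, -g2$t)
  expect_equal(g1$sig_pos, g2$sig_neg)
  expect_equal(g1$sig_neg, g2$sig_pos)
  expect_warning(group_permutation(maps, n_perm = 50, seed = 1),
                 "permutations")
  expect_error(group_permutation(maps[1:4]), "8 subjects")
})

test_that("covariates are regressed out before inference", {
  set.seed(31)
  n <- 14
  age <- runif(n, 18, 39)
  maps <- lapply(1:n, function(i) {
    matrix(0.05 * (age[i] - 28) + rnorm(7 * 20, 0, 0.05), 7, 20)
  })
  cov <- data.frame(age = age)
  g_adj <- group_permutation(maps, covariates = cov, n_perm = 300,
                             seed = 2)
  g_raw <- group_permutation(maps, n_perm = 300, seed = 2)
  expect_equal(g_adj$df, n - 2)
  # adjustment absorbs the age-driven between-subject variance, so the
  # adjusted statistics are sharper
  expect_gt(mean(abs(g_adj$t)), mean(abs(g_raw$t)))
})

test_that("coupled regions are recovered at the planted delay", {
  set.seed(91)
  dims <- c(6, 6, 3)
  nvox <- prod(dims)
  mask_idx <- as.vector(array(seq_len(nvox), dims)[2:4, 2:4, 2])
  n_sub <- 10
  lags <- 0:6
  delay <- 4
  maps <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    run_maps <- vector("list", 3)
    for (r in 1:3) {
      tlr <- run_timeline(run_index = r)
      taps <- simulate_tapping(tlr, clean_params())
      dev <- behavior_deviation(sma(record_iti(taps)))
      reg <- coupling_regressor(tlr, dev, delay = delay)
      bp <- bold_params(grid = dims, noise_sd = 0.35, ar1 = 0.2,
                        effects = list(list(mask = mask_idx, ts = reg,
                                            amplitude = 1)))
      vol <- simulate_bold(tlr, bp)
      ff <- fit_fir(vol, build_fir_design(tlr))
      up <- upsample_betas(ff$betas, ff$times)
      run_maps[[r]] <- lagged_correlation(up, dev, lags = lags)
    }
    maps[[i]] <- average_run_maps(run_maps)
  }
  grp <- group_permutation(maps, n_perm = 500, seed = 7)
  sig_pos <- grp$sig_pos
  mid <- which(lags %in% 3:5)
  expect_gt(sum(sig_pos[mid, mask_idx]), 0)
  expect_equal(sum(sig_pos[, -mask_idx]), 0)
  expect_equal(sum(grp$sig_neg), 0)
})
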