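tl <- run_timeline()

test_that("the block design matches the task structure", {
  des <- build_design(tl)
  expect_equal(des$task_cols,
               c("Sync1", "Sync2", "Cont1", "Cont2", "StopListen",
                 "Rest"))
  expect_equal(length(des$rows), 324L)
  expect_true(all(colSums(abs(des$X[, des$task_cols])) > 0))
  # rest blocks: 6 per run, starting 34 s into each trial
  grid <- seq(0, tl$run_duration, by = 0.01)
  box <- synctap:::phase_boxcar(grid, tl, 34, 54)
  starts <- grid[which(diff(c(0, box)) == 1)]
  expect_equal(starts, tl$trial_onsets + 34, tolerance = 0.01)
  expect_warning(build_design(tl, highpass = 10), "high-pass")
})

test_that("regressor construction matches an independent convolution", {
  des <- build_design(tl, derivatives = FALSE)
  h <- hrf_double_gamma(seq(0, 32, by = 0.01))
  vol_t <- (seq_len(tl$n_volumes) - 1) * tl$tr
  # oracle: direct Riemann sum of hrf over the Cont1 block supports
  oracle <- vapply(vol_t, function(t) {
    s <- 0
    for (on in tl$trial_onsets) {
      u <- seq(on + 6, on + 7.5, by = 0.01)
      s <- s + sum(hrf_double_gamma(t - u)) * 0.01
    }
    s
  }, numeric(1))
  expect_equal(des$X[, "Cont1"], oracle, tolerance = 0.02)
  # the HRF itself: impulse response peaks near 5 s, integrates finitely
  tt <- seq(0, 32, 0.01)
  expect_equal(tt[which.max(hrf_double_gamma(tt))], 5, tolerance = 0.3)
  expect_true(is.finite(sum(hrf_double_gamma(tt)) * 0.01))
  expect_lt(abs(sum(hrf_double_gamma(seq(20, 32, 0.01))) * 0.01), 0.5)
})

test_that("noiseless parameter recovery is exact", {
  des <- build_design(tl)
  mask <- array(FALSE, c(4, 4, 2)); mask[1:4, 1, 1] <- TRUE
  bp <- bold_params(grid = c(4, 4, 2), noise_sd = 0,
                    effects = list(list(mask = mask,
                                        ts = des$X[, "Sync1"],
                                        amplitude = 1)))
  vol <- simulate_bold(tl, bp)
  for (pw in c(FALSE, TRUE)) {
    fit <- fit_glm(vol, des, prewhiten = pw)
    expect_equal(unname(fit$beta["Sync1", 1:4]), rep(1, 4),
                 tolerance = 1e-6)
    expect_lt(max(abs(fit$beta["Sync2", 1:4])), 1e-6)
  }
})

test_that("contrasts behave like linear functionals", {
  set.seed(2)
  des <- build_design(tl)
  vol <- simulate_bold(tl, bold_params(grid = c(4, 4, 2), noise_sd = 1))
  fit <- fit_glm(vol, des, prewhiten = FALSE)
  null_map <- contrast_map(fit, c(Sync1 = 1, Sync1 = -1))
  cpos <- contrast_map(fit, c(Sync1 = 1, Sync2 = -1))
  cneg <- contrast_map(fit, c(Sync1 = -1, Sync2 = 1))
  expect_equal(cpos$z, -cneg$z)
  expect_equal(cpos$effect, -cneg$effect)
  expect_error(contrast_map(fit, c(Bogus = 1)), "unknown")

  # c = Sync1 - Sync1 is the zero functional
  w <- numeric(length(fit$columns)); names(w) <- fit$columns
  w["Sync1"] <- 1 - 1
  expect_true(all(contrast_map(fit, w)$effect == 0))
})

test_that("permuted-time input destroys the task effects", {
  des <- build_design(tl)
  mask <- array(TRUE, c(3, 3, 1))
  bp <- bold_params(grid = c(3, 3, 1), noise_sd = 0.5,
                    effects = list(list(mask = mask,
                                        ts = des$X[, "Sync1"],
                                        amplitude = 2)))
  set.seed(14)
  vol <- simulate_bold(tl, bp)
  fit <- fit_glm(vol, des, prewhiten = FALSE)
  expect_gt(mean(fit$beta["Sync1", ]), 1.5)
  perm <- vol
  perm$data <- perm$data[, , , sample(dim(perm$data)[4]),
                         drop = FALSE]
  fitp <- fit_glm(perm, des, prewhiten = FALSE)
  expect_lt(abs(mean(fitp$beta["Sync1", ])), 0.5)
})

test_that("AR(1) prewhitening yields calibrated null statistics", {
  set.seed(55)
  des <- build_design(tl)
  vol <- simulate_bold(tl, bold_params(grid = c(8, 8, 4), noise_sd = 1,
                                       ar1 = 0.35))
  fit <- fit_glm(vol, des, prewhiten = TRUE)
  # residual-based AR estimates are biased low in short series
  expect_gt(mean(fit$rho), 0.2)
  expect_lt(mean(fit$rho), 0.45)
  z <- as.vector(contrast_map(fit, c(Sync1 = 1, Rest = -1))$z)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(sd(z) - 1), 0.15)
})

test_that("fixed-effects combination matches the closed form", {
  set.seed(9)
  dims <- c(3, 3, 2)
  mk <- function() {
    structure(list(effect = array(rnorm(prod(dims)), dims),
                   var = array(runif(prod(dims), 0.5, 2), dims),
                   z = array(0, dims), df = 100, name = "c"),
              class = "stat_map")
  }
  maps <- list(mk(), mk(), mk())
  comb <- combine_runs_fixed_effects(maps)
  # oracle: inverse-variance meta-analytic formulas, element by element
  w <- lapply(maps, function(m) 1 / m$var)
  wsum <- Reduce(`+`, w)
  eff <- Reduce(`+`, Map(function(m, wi) wi * m$effect, maps, w)) / wsum
  expect_equal(comb$effect, eff)
  expect_equal(comb$var, 1 / wsum)

  # identical runs: same effect, variance / 3
  same <- list(maps[[1]], maps[[1]], maps[[1]])
  cs <- combine_runs_fixed_effects(same)
  expect_equal(cs$effect, maps[[1]]$effect)
  expect_equal(cs$var, maps[[1]]$var / 3)

  # a run with huge variance gets negligible weight
  noisy <- maps
  noisy[[3]]$var[] <- 1e12
  cn <- combine_runs_fixed_effects(noisy)
  expect_equal(cn$effect, combine_runs_fixed_effects(maps[1:2])$effect,
               tolerance = 1e-6)
})

test_that("cluster labelling matches a reference flood fill", {
  set.seed(77)
  for (rep in 1:10) {
    m <- array(runif(6 * 5 * 4) < 0.3, c(6, 5, 4))
    lab <- label_clusters(m)
    expect_equal(lab > 0, m)
    # oracle: recursive flood fill
    seen <- array(FALSE, dim(m))
    sizes <- integer(0)
    for (i in which(m)) {
      if (seen[i]) next
      queue <- i; seen[i] <- TRUE; sz <- 0
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]; sz <- sz + 1
        co <- arrayInd(v, dim(m))
        for (ax in 1:3) for (dd in c(-1, 1)) {
          nb <- co; nb[ax] <- nb[ax] + dd
          if (nb[ax] < 1 || nb[ax] > dim(m)[ax]) next
          j <- nb[1] + (nb[2] - 1) * dim(m)[1] +
            (nb[3] - 1) * dim(m)[1] * dim(m)[2]
          if (m[j] && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
        }
      }
      sizes <- c(sizes, sz)
    }
    expect_equal(sort(cluster_sizes(lab)), sort(sizes))
    # same label iff same component
    for (k in seq_len(max(lab))) {
      vx <- which(lab == k)
      expect_true(all(lab[vx] == k))
    }
  }
})

test_that("group inference recovers planted effects and ignores null maps", {
  dims <- c(8, 8, 4)
  n <- 12
  mask <- array(FALSE, dims); mask[3:6, 3:6, 2:3] <- TRUE
  set.seed(33)
  arr <- array(rnorm(prod(dims) * n, 0, 1), c(dims, n))
  arr[, , , ] <- arr + as.vector(mask) * 2.5
  gs <- group_stats(arr, n_perm = 300, seed = 3)
  expect_gt(sum(gs$sig_mask & mask) / sum(mask), 0.9)
  expect_equal(sum(gs$sig_mask & !mask), 0)

  zero <- array(0, c(dims, n))
  gz <- group_stats(zero, n_perm = 100, seed = 1)
  expect_equal(nrow(gz$clusters), 0L)
  expect_error(group_stats(arr[, , , 1:4, drop = FALSE]), "8 subjects")
})
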