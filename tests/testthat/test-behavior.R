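mk_series <- function(time, value, trial = 1L, valid = TRUE,
                      kind = "iti") {
  out <- data.frame(trial = rep_len(trial, length(time)), time = time,
                    value = value, valid = rep_len(valid, length(time)))
  attr(out, "kind") <- kind
  class(out) <- c("measurement_series", class(out))
  out
}

test_that("sliding-window average matches its definition on simple input", {
  s <- mk_series(3.0, 42)
  out <- sma(s, sma_params())
  expect_equal(out$mean[out$center >= 2 & out$center <= 4], rep(42, 5))
  expect_true(all(is.na(out$mean[out$center < 2 | out$center > 4])))
  expect_equal(out$n[out$center == 3], 1)

  s2 <- mk_series(seq(0.25, 25.75, by = 0.5), 500)
  out2 <- sma(s2)
  expect_true(all(out2$mean[!is.na(out2$mean)] == 500))
  # closed membership on both sides
  s3 <- mk_series(c(1, 3), c(10, 20))
  expect_equal(sma(s3, sma_params(grid = 2))$mean, 15)
})

test_that("sliding-window average equals a brute-force oracle", {
  set.seed(99)
  params <- sma_params()
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    s <- mk_series(runif(n, 0, 26), rnorm(n, 500, 30),
                   valid = runif(n) > 0.2)
    out <- sma(s, params)
    v <- s[s$valid, ]
    for (i in seq_along(params$grid)) {
      inw <- v$value[abs(v$time - params$grid[i]) <= params$half_width]
      if (length(inw)) {
        expect_equal(out$mean[i], mean(inw))
        expect_equal(out$n[i], length(inw))
      } else {
        expect_true(is.na(out$mean[i]))
      }
    }
  }
})

test_that("empty series give all-missing curves, not errors", {
  s <- mk_series(numeric(0), numeric(0))
  out <- sma(s)
  expect_true(all(is.na(out$mean)))
})

test_that("event-based averaging aligns taps with the tone grid", {
  curves <- do.call(rbind, lapply(1:5, function(s) {
    data.frame(subject = s, index = 1:10, value = 500 + (1:10))
  }))
  out <- event_based_average(curves)
  expect_equal(out$mean, 500 + (1:10))
  expect_equal(out$time, (1:10) * 0.5)
  expect_equal(out$sd, rep(0, 10))

  # a subject tapping 10% slow diverges late in index-aligned time
  tlr <- run_timeline()
  slow <- quiet_params(target_period = 550)
  taps <- simulate_tapping(tlr, slow)
  ti <- tap_indexed(record_iti(taps))
  # once self-paced, the index-aligned curve sits at 550 while its
  # wall-clock time drifts: tap n occurs near n * 0.55 s, not n * 0.5 s
  expect_true(all(abs(utils::tail(ti$value, 10) - 550) < 1e-6))
  cont_taps <- taps$onset[taps$trial == 1][-(1:12)]
  expect_true(all(diff(cont_taps) > 0.549))
})

test_that("cell aggregation reproduces known means and CVs", {
  tlr <- run_timeline()
  taps <- simulate_tapping(tlr, quiet_params())
  iti <- record_iti(taps)
  iti$subject <- "s1"; iti$run <- 1L
  cells <- aggregate_cells(iti)
  expect_true(all(abs(cells$mean_iti - 500) < 1e-9))
  expect_true(all(cells$cv_iti[cells$n_valid > 1] < 1e-12))
  # permutation invariance
  set.seed(12)
  cells2 <- aggregate_cells(iti[sample(nrow(iti)), ])
  expect_equal(cells, cells2)
})

test_that("force CV is invariant to rescaling", {
  set.seed(3)
  f <- mk_series(seq(0.5, 25.5, 0.5), rlnorm(51, log(5000), 0.2),
                 kind = "force")
  f$subject <- "s1"; f$run <- 1L
  i <- mk_series(seq(0.5, 25.5, 0.5), rnorm(51, 500, 20))
  i$subject <- "s1"; i$run <- 1L
  c1 <- aggregate_cells(i, f)
  f10 <- f; f10$value <- f10$value * 10
  c2 <- aggregate_cells(i, f10)
  expect_equal(c1$cv_force, c2$cv_force)
  expect_equal(c2$mean_force, 10 * c1$mean_force)
})

test_that("covariate residualization removes planted effects", {
  set.seed(8)
  n <- 40
  cov <- data.frame(subject = sprintf("s%02d", 1:n),
                    age = runif(n, 18, 39),
                    sex = sample(c("F", "M"), n, replace = TRUE))
  cells <- data.frame(subject = rep(cov$subject, each = 2),
                      condition = rep(c("sync", "cont"), n),
                      phase = "all", run = 1L, trial = 1L)
  cells$mean_iti <- 500 + 2 * (cov$age[match(cells$subject,
                                             cov$subject)] - 25) +
    rnorm(nrow(cells), 0, 0.5)
  out <- residualize_covariates(cells, cov, metrics = "mean_iti")
  r <- cor(out$mean_iti, cov$age[match(out$subject, cov$subject)])
  expect_lt(abs(r), 1e-8)
  expect_equal(mean(out$mean_iti), mean(cells$mean_iti))

  # orthogonal covariate leaves the metric unchanged
  cells0 <- cells
  cells0$mean_iti <- rep(c(490, 510), n)
  cov0 <- cov
  cov0$age <- rep(c(20, 30), n / 2)[order(rep(1:n, 1))]
  out0 <- residualize_covariates(cells0, cov,
                                 metrics = "mean_iti",
                                 covars = "age")
  expect_equal(sd(out0$mean_iti), sd(cells0$mean_iti), tolerance = 0.05)

  cov$sex <- "F"
  expect_error(residualize_covariates(cells, cov), "rank")

})

test_that("repeated-measures ANOVA detects planted condition effects", {
  set.seed(5)
  n <- 16
  grid <- expand.grid(subject = sprintf("s%02d", 1:n),
                      condition = c("sync", "cont"), run = 1:3,
                      trial = 1:3)
  subj_fx <- rnorm(n, 0, 5)
  grid$mean_iti <- 500 + ifelse(grid$condition == "cont", 8, 0) +
    subj_fx[as.integer(factor(grid$subject))] + rnorm(nrow(grid), 0, 4)
  grid$phase <- "all"
  an <- rm_anova(grid, dv = "mean_iti",
                 factors = c("condition", "run", "trial"))
  pc <- an$table$p[an$table$effect == "condition"]
  expect_lt(pc, 0.001)
  ph <- an$posthoc$condition
  expect_equal(nrow(ph), 1L)
  expect_lt(ph$p_adj, 0.001)
  expect_equal(abs(ph$diff), 8, tolerance = 3)

  # duplicated identical conditions: the condition effect vanishes
  dup <- grid
  dup$mean_iti[dup$condition == "cont"] <-
    dup$mean_iti[dup$condition == "sync"]
  an2 <- rm_anova(dup, dv = "mean_iti",
                  factors = c("condition", "run", "trial"))
  expect_lt(abs(an2$posthoc$condition$diff), 1e-9)

  expect_error(rm_anova(grid[grid$condition == "sync", ],
                        dv = "mean_iti",
                        factors = c("condition", "run")), "levels")
})

test_that("subjects with incomplete cells are dropped and reported", {
  set.seed(6)
  n <- 10
  grid <- expand.grid(subject = sprintf("s%02d", 1:n),
                      condition = c("sync", "cont"), run = 1:2)
  grid$trial <- 1L
  grid$mean_iti <- rnorm(nrow(grid), 500, 5)
  grid <- grid[!(grid$subject == "s01" & grid$condition == "cont"), ]
  an <- rm_anova(grid, dv = "mean_iti", factors = c("condition", "run"))
  expect_equal(an$dropped, "s01")
  expect_equal(an$n_subjects, n - 1L)
})
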