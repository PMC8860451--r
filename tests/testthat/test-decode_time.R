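make_intervals <- function(signals, licks = NULL, fs = 100) {
  n <- length(signals)
  licks <- licks %||% rep(3, n)
  iv <- tibble::tibble(
    trial = seq_len(n),
    first_lick_time = licks,
    t0 = 10 + seq_len(n) * 20 + 0.7,
    t1 = 10 + seq_len(n) * 20 + 0.7 + lengths(signals) / fs,
    valid = lengths(signals) > 0,
    signal = signals
  )
  attr(iv, "fs") <- fs
  class(iv) <- c("ramping_intervals", class(iv))
  iv
}

test_that("debounced crossings handle lines, ties and non-crossers", {
  ramp <- seq(0, 1, length.out = 101)
  iv <- make_intervals(list(ramp))
  cr <- debounced_crossing_times(iv, 0.5)
  expect_true(cr$crossed)
  expect_lt(abs(cr$norm_time - 0.5), 0.02)
  # starts and ends above the level: no crossing
  iv2 <- make_intervals(list(ramp + 2))
  expect_false(debounced_crossing_times(iv2, 0.5)$crossed)
  expect_equal(debounced_crossing_times(iv2, 0.5)$norm_time, 0)
  # ends below the level: no crossing
  iv3 <- make_intervals(list(rev(ramp)))
  expect_false(debounced_crossing_times(iv3, 0.5)$crossed)
})

test_that("crossing times agree with a brute-force suffix-scan oracle", {
  set.seed(40)
  oracle_cross <- function(v, level) {
    for (i in seq_along(v)) {
      if (all(v[i:length(v)] >= level) &&
          (i > 1 && v[i - 1] < level)) return(i)
      if (i == 1 && all(v >= level)) {
        return(if (v[1] <= level) 1L else 0L)   # at-level start crosses
      }
    }
    0L
  }
  sigs <- lapply(1:100, function(i) cumsum(rnorm(150, mean = 0.01)))
  iv <- make_intervals(sigs)
  for (level in c(-0.2, 0.3, 0.8)) {
    got <- debounced_crossing_times(iv, level)
    want <- vapply(sigs, oracle_cross, integer(1), level = level)
    expect_equal(got$norm_time,
                 ifelse(want > 0, want / lengths(sigs), 0),
                 tolerance = 1e-12)
  }
})

test_that("threshold selection follows the crossing-count rules", {
  # identical ramps: every level crossed by all trials; mid is the lowest level
  ramps <- replicate(60, seq(0, 1, length.out = 80), simplify = FALSE)
  iv <- make_intervals(ramps)
  ts <- select_thresholds(iv)
  expect_equal(ts$mid$level, ts$levels[1])
  expect_equal(ts$mid$n_crossing, 60L)

  # 60 ramps + 40 flat-low trials: min/mid/max all carry 60 crossings
  flats <- replicate(40, rep(-0.5, 80), simplify = FALSE)
  iv2 <- make_intervals(c(ramps, flats))
  ts2 <- select_thresholds(iv2)
  expect_equal(ts2$min$n_crossing, 60L)
  expect_equal(ts2$mid$n_crossing, 60L)
  expect_equal(ts2$max$n_crossing, 60L)
  expect_equal(ts2$min$level, min(ts2$levels[ts2$crossings >= 50]))

  # pure noise with relaxed selection: picks the most-crossed level
  set.seed(41)
  noise <- lapply(1:30, function(i) rnorm(80))
  iv3 <- make_intervals(noise)
  ts3 <- select_thresholds(iv3, relaxed = TRUE)
  expect_true(ts3$relaxed)
  expect_lte(ts3$mid$n_crossing, 30L)
})

test_that("crossing operator is invariant to monotone rescaling", {
  set.seed(42)
  sigs <- lapply(1:20, function(i) cumsum(rnorm(120, 0.02)))
  iv_a <- make_intervals(sigs)
  iv_b <- make_intervals(lapply(sigs, function(v) 3 * v + 10))
  a <- debounced_crossing_times(iv_a, 0.5)
  b <- debounced_crossing_times(iv_b, 3 * 0.5 + 10)
  expect_equal(a$norm_time, b$norm_time)
})

test_that("the nested decoder recovers an exact log-linear relationship", {
  set.seed(43)
  n <- 120
  crossing <- runif(n, 0.1, 1)
  y <- 0.3 + 0.9 * crossing          # log first-lick time, exactly linear
  X <- cbind(x0 = 1, prev_lick = runif(n), out_reaction = rbinom(n, 1, .1),
             out_early = rbinom(n, 1, .4), out_reward = rbinom(n, 1, .4),
             out_iti = rbinom(n, 1, .05), iti_median = runif(n),
             loi_median = runif(n), control_cross = runif(n),
             signal_cross = crossing)
  fit <- ramptime:::nested_ridge(y, X, groups = colnames(X),
                                 ramptime:::decoder_groups,
                                 fold_id = seq_len(n), seed = 1)
  var_y <- mean((y - mean(y))^2)
  r2_cv <- 1 - fit$nests$test_loss / var_y
  expect_gt(r2_cv[10], 0.99)         # final nest explains everything
  expect_lt(max(r2_cv[1:9]), 0.2)    # earlier nests carry no signal
})

test_that("decoder on ramp sessions gains most from the crossing nest", {
  s <- ramp_session_250()
  fit <- fit_timelick_decoder(s, session_dff(s), session_dff(s, "control"),
                              seed = 3)
  r2 <- fit$nests$r_squared_cv
  n <- nrow(fit$nests)
  expect_gt(r2[n], 0.3)
  # the signal-crossing nest still improves held-out R^2 on top of baselines
  expect_gt(r2[n] - r2[n - 1], 0.02)

  # absorption: with the crossing nest fitted first, the baseline (LOI)
  # nest's marginal gain shrinks relative to the printed order
  dat0 <- attr(fit, "decoder_data")
  X0 <- cbind(x0 = 1, as.matrix(dat0[setdiff(ramptime:::decoder_groups, "x0")]))
  alt_order <- c("x0", "signal_cross", "loi_median")
  fit_alt <- ramptime:::nested_ridge(dat0$y, X0[, c("x0", "signal_cross", "loi_median")],
                                     groups = c("x0", "signal_cross", "loi_median"),
                                     alt_order, fold_id = dat0$trial, seed = 5)
  fit_std <- ramptime:::nested_ridge(dat0$y, X0[, c("x0", "loi_median", "signal_cross")],
                                     groups = c("x0", "loi_median", "signal_cross"),
                                     c("x0", "loi_median", "signal_cross"),
                                     fold_id = dat0$trial, seed = 5)
  var_y <- mean((dat0$y - mean(dat0$y))^2)
  gain_loi_after <- (fit_alt$nests$test_loss[2] - fit_alt$nests$test_loss[3]) / var_y
  gain_loi_before <- (fit_std$nests$test_loss[1] - fit_std$nests$test_loss[2]) / var_y
  expect_lt(gain_loi_after, gain_loi_before)
  # shuffled response: no nest explains anything
  set.seed(44)
  dat <- attr(fit, "decoder_data")
  yper <- sample(dat$y)
  Xd <- cbind(x0 = 1, as.matrix(dat[setdiff(ramptime:::decoder_groups, "x0")]))
  fit0 <- ramptime:::nested_ridge(yper, Xd, groups = colnames(Xd),
                                  ramptime:::decoder_groups,
                                  fold_id = dat$trial, seed = 4)
  r2_0 <- 1 - fit0$nests$test_loss / mean((yper - mean(yper))^2)
  expect_lt(max(r2_0), 0.1)
})

test_that("slope profiles separate ramp from step dynamics", {
  # ideal single-step trials: crossing time is the step time at every level
  set.seed(45)
  licks <- runif(80, 2.2, 5)
  step_sigs <- lapply(licks, function(T_) {
    n <- round((T_ - 1.3) * 100)
    st <- round(0.5 * n)             # step at a fixed fraction of the trial
    c(rep(0, st), rep(1, n - st))
  })
  iv_s <- make_intervals(step_sigs, licks = licks)
  ts_s <- list(min = list(level = 0.2), mid = list(level = 0.5),
               max = list(level = 0.8))
  sl_s <- threshold_slope_analysis(iv_s, ts_s)
  expect_lt(diff(range(sl_s$slope)), 0.05)

  # common-endpoint ramps: slope grows with level
  ramp_sigs <- lapply(licks, function(T_) {
    n <- round((T_ - 1.3) * 100)
    seq(0, 1, length.out = n)
  })
  iv_r <- make_intervals(ramp_sigs, licks = licks)
  sl_r <- threshold_slope_analysis(iv_r, ts_s)
  expect_true(all(diff(sl_r$slope) > 0))
})
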