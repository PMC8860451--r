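test_that("first-lick draws honour the scalar timing property", {
  t1 <- sample_first_lick_times(10000, mean = 3.3, weber_fraction = 0.3, seed = 1)
  t2 <- sample_first_lick_times(10000, mean = 5.0, weber_fraction = 0.3, seed = 2)
  cv1 <- sd(t1) / mean(t1)
  cv2 <- sd(t2) / mean(t2)
  expect_lt(abs(cv1 / cv2 - 1), 0.03)
  expect_equal(mean(t1), 3.3, tolerance = 0.02)
  expect_equal(mean(t2), 5.0, tolerance = 0.02)
  # degenerate-variance limit collapses on the mean
  t0 <- sample_first_lick_times(100, mean = 3.3, weber_fraction = 1e-6, seed = 3)
  expect_true(all(abs(t0 - 3.3) < 1e-4))
  # determinism contract
  expect_identical(
    sample_first_lick_times(50, 3.3, 0.3, seed = 9),
    sample_first_lick_times(50, 3.3, 0.3, seed = 9))
  expect_error(sample_first_lick_times(10, -1, 0.3), "positive")
  expect_error(sample_first_lick_times(10, 3.3, 0), "positive")
})

test_that("trial timeline assigns windows, delays and outcomes consistently", {
  cfg <- task_config()
  tt <- build_trial_timeline(c(0.4, 3.2, 3.4, 8, NA), cfg, seed = 1)
  expect_equal(as.character(tt$outcome),
               c("reaction", "early", "reward", "iti_lick", "no_lick"))
  delays <- tt$cue_time - tt$lampoff_time
  expect_true(all(delays >= cfg$lampoff_delay_range[1] &
                    delays <= cfg$lampoff_delay_range[2]))
  # every trial gets exactly one outcome
  expect_false(anyNA(tt$outcome))
})

test_that("a unit hazard multiplier leaves the first-lick law unchanged", {
  pvals <- vapply(1:30, function(s) {
    times <- sample_first_lick_times(400, 3.3, 0.3, seed = s)
    tt <- build_trial_timeline(times, task_config(),
                               opto = list(fraction = 0.3, hazard_multiplier = 1),
                               seed = s + 1000)
    suppressWarnings(stats::ks.test(
      tt$first_lick_time[tt$opto_on],
      tt$first_lick_time[!tt$opto_on])$p.value)
  }, numeric(1))
  # p-values approximately uniform under the null
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(mean(pvals > 0.05), 0.8)
})

test_that("a hazard multiplier above one early-shifts redrawn licks", {
  times <- sample_first_lick_times(2000, 3.3, 0.3, seed = 4)
  tt <- build_trial_timeline(times, task_config(),
                             opto = list(fraction = 0.3, hazard_multiplier = 2),
                             seed = 5)
  expect_lt(median(tt$first_lick_time[tt$opto_on], na.rm = TRUE),
            median(tt$first_lick_time[!tt$opto_on], na.rm = TRUE))
})

test_that("noiseless ramp-mode trials hit the common endpoint amplitude", {
  gp <- generative_params(
    n_trials = 12, noise_sd = 0, artifact_rate = 0,
    cue_kernel = list(amplitude = 0, rise = 0.02, decay = 0.1),
    lick_kernel = list(amplitude = 0, rise = 0.05, decay = 0.1),
    reward_kernel = list(amplitude = 0, rise = 0.03, decay = 0.25),
    bleach_tau = 1e9)
  cfg <- task_config(sampling_rate = 500)
  s <- simulate_session(gp, cfg, seed = 6)
  fs <- cfg$sampling_rate
  for (i in seq_len(nrow(s$trials))) {
    T_i <- s$trials$first_lick_time[i]
    if (is.na(T_i) || T_i <= gp$ramp_onset_lag + 0.1) next
    cue <- s$trials$cue_time[i]
    onset_idx <- round((cue + gp$ramp_onset_lag) * fs) + 1
    lick_idx <- round((cue + T_i) * fs) + 1
    rise <- s$channels$gcamp[lick_idx] - s$channels$gcamp[onset_idx]
    slope <- gp$ramp_peak_amplitude / (T_i - gp$ramp_onset_lag)
    expect_equal(rise, gp$ramp_peak_amplitude, tolerance = 2 * slope / fs)
  }
})

test_that("step-mode latencies are uniform and pooled averages rise linearly", {
  gp <- generative_params(
    n_trials = 1200, dynamics_mode = "step", noise_sd = 0,
    artifact_rate = 0, bleach_tau = 1e9,
    cue_kernel = list(amplitude = 0, rise = 0.02, decay = 0.1),
    lick_kernel = list(amplitude = 0, rise = 0.05, decay = 0.1),
    reward_kernel = list(amplitude = 0, rise = 0.03, decay = 0.25))
  times <- sample_first_lick_times(gp$n_trials, gp$mean_move_time,
                                   gp$weber_fraction, seed = 7)
  trials <- build_trial_timeline(times, task_config(sampling_rate = 100),
                                 seed = 8)
  s <- synthesize_session(trials, gp, task_config(sampling_rate = 100),
                          seed = 9)
  frac <- s$trials$gt_step_time / s$trials$first_lick_time
  frac <- frac[!is.na(frac)]
  expect_gt(length(frac), 1000)
  expect_gt(stats::ks.test(frac, "punif")$p.value, 0.01)

  # cue-aligned average of uniformly timed steps approximates a linear ramp
  keep <- which(!is.na(s$trials$first_lick_time) &
                  abs(s$trials$first_lick_time - 3) < 0.5)
  fs <- 100
  rel <- seq(0, round(2.4 * fs))
  M <- vapply(keep, function(i) {
    s$channels$gcamp[round(s$trials$cue_time[i] * fs) + 1 + rel]
  }, numeric(length(rel)))
  avg <- rowMeans(M)
  smoothed <- stats::filter(avg, rep(1 / 15, 15))
  d <- diff(stats::na.omit(as.numeric(smoothed)))
  expect_gt(mean(d > -1e-9), 0.95)  # monotone non-decreasing within noise
  # analytic mean: amplitude * P(step before t) = A * t / T for t < T
  tmid <- round(1.2 * fs)
  expected <- gp$ramp_peak_amplitude * (tmid / fs) / 3
  base <- mean(M[1, ])
  expect_equal(avg[tmid + 1] - base, expected, tolerance = 0.25)
})

test_that("the control channel carries no timing structure", {
  s <- ramp_session_250()
  fs <- s$config$sampling_rate
  keep <- which(!is.na(s$trials$first_lick_time) &
                  s$trials$first_lick_time > 1.5)
  ctl_mean <- vapply(keep, function(i) {
    i0 <- round((s$trials$cue_time[i] + 0.7) * fs) + 1
    i1 <- round((s$trials$cue_time[i] + s$trials$first_lick_time[i] - 0.6) * fs) + 1
    mean(s$channels$control[i0:max(i0, i1)])
  }, numeric(1))
  fit <- stats::lm(ctl_mean ~ s$trials$first_lick_time[keep])
  ci <- stats::confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("identical seeds give bit-identical sessions", {
  gp <- generative_params(n_trials = 8)
  cfg <- task_config(sampling_rate = 100)
  s1 <- simulate_session(gp, cfg, seed = 11)
  s2 <- simulate_session(gp, cfg, seed = 11)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$events, s2$events)
})

test_that("baseline offsets anticorrelate with move time as designed", {
  s <- ramp_session_250()
  tr <- s$trials[!is.na(s$trials$first_lick_time), ]
  expect_lt(cor(tr$gt_baseline_offset, tr$first_lick_time), -0.4)
  expect_lt(cor(log(tr$gt_baseline_offset), log(tr$first_lick_time)), -0.7)
})
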