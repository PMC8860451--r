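test_that("hypothesis scores equal an independent log-density oracle", {
  set.seed(50)
  fs <- 100
  y <- ramptime:::minmax_scale(cumsum(rnorm(120, 0.01)))
  ctx <- ramptime:::trial_context(y, fs)
  h_r <- list(class = "ramp", slope = 0.2, intercept = 0.1, sigma = 0.15)
  got <- score_hypothesis(y, h_r, fs)
  t <- (seq_along(y) - 1) / fs
  ab <- ramptime:::beta_from_mode(sd(y))
  oracle <- dnorm(h_r$slope, 0, ctx$slope_sd, log = TRUE) +
    dnorm(h_r$intercept, mean(y), 1, log = TRUE) +
    dbeta(h_r$sigma, ab["a"], ab["b"], log = TRUE) +
    sum(dnorm(y - (h_r$slope * t + h_r$intercept), 0, h_r$sigma, log = TRUE))
  expect_equal(got, unname(oracle), tolerance = 1e-10)

  h_s <- list(class = "step", steptime = 0.5, left = 0.2, right = 0.8,
              sigma = 0.2)
  got_s <- score_hypothesis(y, h_s, fs)
  mu <- ifelse(t < 0.5, h_s$left, h_s$right)
  oracle_s <- -log(length(ctx$step_idx)) +
    dnorm(h_s$left, mean(y), 1, log = TRUE) +
    dnorm(h_s$right, mean(y), 1, log = TRUE) +
    dbeta(h_s$sigma, ab["a"], ab["b"], log = TRUE) +
    sum(dnorm(y - mu, 0, h_s$sigma, log = TRUE))
  expect_equal(got_s, unname(oracle_s), tolerance = 1e-10)
  # zero residuals at fixed sigma: closed-form Gaussian likelihood
  flat <- rep(0.4, 50)
  h0 <- list(class = "step", steptime = 0.25, left = 0.4, right = 0.4,
             sigma = 0.1)
  ll <- score_hypothesis(flat, h0, fs)
  ctx0 <- ramptime:::trial_context(flat, fs)
  expect_equal(ll - (-log(length(ctx0$step_idx)) +
                       dnorm(0.4, 0.4, 1, log = TRUE) * 2 +
                       dbeta(0.1, ramptime:::beta_from_mode(0)["a"],
                             ramptime:::beta_from_mode(0)["b"], log = TRUE)),
               -50 * log(0.1 * sqrt(2 * pi)), tolerance = 1e-8)
  # invalid noise scores -Inf
  expect_identical(score_hypothesis(y, modifyList(h_r, list(sigma = 0)), fs),
                   -Inf)
})

test_that("maxslope is the data range over the duration", {
  fs <- 50
  y <- c(seq(0, 1, length.out = 100), seq(1, 0.4, length.out = 20))
  ctx <- ramptime:::trial_context(y, fs)
  expect_equal(ctx$maxslope, (max(y) - min(y)) / ((length(y) - 1) / fs),
               tolerance = 1e-12)
})

test_that("ramp proposals centre on the underlying line", {
  fs <- 100
  t <- seq(0, 1.2, by = 1 / fs)
  y <- 0.1 * t + 0.2
  draws <- t(vapply(1:100, function(s) {
    h <- propose_ramp(y, fs, seed = s)
    c(h$slope, h$intercept)
  }, numeric(2)))
  expect_lt(abs(mean(draws[, 1]) - 0.1), 0.01 + 0.1 * 0.1)
  expect_lt(abs(mean(draws[, 2]) - 0.2), 0.02 + 0.1 * 0.2)
})

test_that("step proposals track derivative peaks and segment means", {
  fs <- 100
  y <- c(rep(0.1, 60), rep(0.9, 60))
  hits <- vapply(1:100, function(s) propose_step(y, fs, seed = s)$steptime,
                 numeric(1))
  expect_gte(mean(abs(hits - 0.6) <= 5 / fs), 0.95)
  h <- propose_step(y, fs, seed = 1)
  expect_lt(abs(h$left - 0.1), 0.05)
  expect_lt(abs(h$right - 0.9), 0.05)
  # a clean line has no single derivative peak: steptimes spread out
  ramp <- seq(0, 1, length.out = 120)
  spread <- vapply(1:100, function(s) propose_step(ramp, fs, seed = s)$steptime,
                   numeric(1))
  expect_gt(diff(range(spread)), 0.3)
})

test_that("sigma proposals concentrate around the stated Beta mode", {
  set.seed(51)
  ab <- ramptime:::beta_from_mode(0.2)
  draws <- rbeta(20000, ab["a"], ab["b"])
  dens <- density(draws, from = 0.01, to = 0.99)
  expect_lt(abs(dens$x[which.max(dens$y)] - 0.2), 0.05)
})

test_that("classification separates clean ramps from clean steps", {
  set.seed(52)
  fs <- 100
  n_tr <- 40
  ramps <- lapply(1:n_tr, function(i) {
    n <- sample(120:250, 1)
    seq(0, 1, length.out = n) + rnorm(n, 0, 0.05)
  })
  steps <- lapply(1:n_tr, function(i) {
    n <- sample(120:250, 1)
    st <- sample(seq(20, n - 20), 1)
    c(rep(0, st), rep(1, n - st)) + rnorm(n, 0, 0.05)
  })
  p_ramp_r <- vapply(seq_along(ramps), function(i)
    classify_trial(ramps[[i]], fs, seed = 100 + i)$p_ramp, numeric(1))
  p_ramp_s <- vapply(seq_along(steps), function(i)
    classify_trial(steps[[i]], fs, seed = 200 + i)$p_ramp, numeric(1))
  expect_gte(median(p_ramp_r), 0.8)
  expect_lte(median(p_ramp_s), 0.2)
  expect_gte(mean(p_ramp_r >= 0.5), 0.8)
  expect_gte(mean(p_ramp_s <= 0.5), 0.8)
})

test_that("near-zero SNR trials are ambiguous", {
  set.seed(53)
  p <- vapply(1:30, function(i) {
    classify_trial(rnorm(150, 0.5, 0.2), 100, seed = 300 + i)$p_ramp
  }, numeric(1))
  expect_gt(mean(p), 0.15)
  expect_lt(mean(p), 0.85)
})

test_that("p_ramp is invariant to affine rescaling of the signal", {
  set.seed(54)
  y <- seq(0, 1, length.out = 150) + rnorm(150, 0, 0.05)
  a <- classify_trial(y, 100, seed = 7)$p_ramp
  b <- classify_trial(5 * y + 20, 100, seed = 7)$p_ramp
  expect_identical(a, b)
})

test_that("retain-best refinement never decreases the best score", {
  set.seed(55)
  y <- seq(0, 1, length.out = 140) + rnorm(140, 0, 0.1)
  cl <- classify_trial(y, 100, seed = 8)
  for (path in cl$best_score_path) {
    expect_true(all(diff(path) >= 0))
  }
})

test_that("step-aligned averages discriminate the two dynamics", {
  set.seed(56)
  fs <- 100
  n_tr <- 50
  make_iv <- function(signals, licks) {
    iv <- tibble::tibble(
      trial = seq_along(signals), first_lick_time = licks,
      t0 = 0.7, t1 = 0.7 + lengths(signals) / fs,
      valid = TRUE, signal = signals)
    attr(iv, "fs") <- fs
    class(iv) <- c("ramping_intervals", class(iv))
    iv
  }
  licks <- runif(n_tr, 3, 4.5)
  st_frac <- runif(n_tr, 0.25, 0.75)
  steps <- lapply(1:n_tr, function(i) {
    n <- round((licks[i] - 1.3) * fs)
    st <- round(st_frac[i] * n)
    c(rep(0, st), rep(1, n - st)) + rnorm(n, 0, 0.04)
  })
  iv_s <- make_iv(steps, licks)
  cl_s <- classify_session(iv_s, seed = 9)
  avg_s <- step_aligned_average(iv_s, cl_s$best_step_time, window = 0.8)
  # clean step: fast 10-90% rise around the alignment point
  pre <- mean(avg_s$mean[avg_s$t < -0.15], na.rm = TRUE)
  post <- mean(avg_s$mean[avg_s$t > 0.15], na.rm = TRUE)
  expect_gt(post - pre, 0.7)
  # background slope away from the step is near zero
  bg <- lm(mean ~ t, data = avg_s[avg_s$t > 0.2, ])
  expect_lt(abs(coef(bg)[2]), 0.25)

  ramps <- lapply(1:n_tr, function(i) {
    n <- round((licks[i] - 1.3) * fs)
    seq(0, 1, length.out = n) + rnorm(n, 0, 0.04)
  })
  iv_r <- make_iv(ramps, licks)
  cl_r <- classify_session(iv_r, seed = 10)
  avg_r <- step_aligned_average(iv_r, cl_r$best_step_time, window = 0.8)
  bg_r <- lm(mean ~ t, data = avg_r[abs(avg_r$t) > 0.2, ])
  expect_gt(coef(bg_r)[2], 0.1)   # residual background ramping

  # single trial: the average is the trial itself, shifted
  one <- make_iv(ramps[1], licks[1])
  avg1 <- step_aligned_average(one, 1.0, window = 0.3)
  v <- ramps[[1]]
  i0 <- round(1.0 * fs) + 1
  expect_equal(avg1$mean[avg1$t == 0], v[i0])
})

test_that("variance profiles separate uniform steps from common-endpoint ramps", {
  set.seed(57)
  fs <- 100
  n_tr <- 120
  licks <- runif(n_tr, 2.2, 3.8)
  make_iv <- function(signals, licks) {
    iv <- tibble::tibble(
      trial = seq_along(signals), first_lick_time = licks,
      t0 = 0.7, t1 = 0.7 + lengths(signals) / fs,
      valid = TRUE, signal = signals)
    attr(iv, "fs") <- fs
    class(iv) <- c("ramping_intervals", class(iv))
    iv
  }
  steps <- lapply(1:n_tr, function(i) {
    n <- round((licks[i] - 1.3) * fs)
    st <- sample.int(n - 2, 1) + 1
    c(rep(0, st), rep(1, n - st)) + rnorm(n, 0, 0.03)
  })
  vp_s <- step_variance_profile(make_iv(steps, licks), min_pool = 20)
  expect_lt(vp_s$curvature, 0)     # inverted U

  # common-endpoint ramps with baseline-offset noise in a tight lick pool:
  # cross-trial variance shrinks as the trials converge on the endpoint
  licks_r <- runif(n_tr, 3.2, 3.4)
  ramps <- lapply(1:n_tr, function(i) {
    n <- round((licks_r[i] - 1.3) * fs)
    seq(rnorm(1, 0.2, 0.1), 1, length.out = n) + rnorm(n, 0, 0.03)
  })
  vp_r <- step_variance_profile(make_iv(ramps, licks_r), min_pool = 20)
  expect_lt(vp_r$spearman_rho, -0.5)  # variance falls toward the lick

  # noise-free identical trials: zero variance everywhere
  same <- lapply(1:60, function(i) seq(0, 1, length.out = 200))
  vp_0 <- step_variance_profile(make_iv(same, rep(3.3, 60)), min_pool = 20)
  expect_lt(max(vp_0$profile$variance), 1e-20)
})
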