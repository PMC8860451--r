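test_that("ridge coefficients match the closed form and an optimiser", {
  set.seed(20)
  X <- matrix(rnorm(50 * 5), 50, 5)   # 50 timepoints, 5 predictors
  theta <- c(2, -1, 0.5, 0, 3)
  Y <- as.numeric(X %*% theta) + rnorm(50, sd = 0.1)
  lambda <- 0.7
  got <- ramptime:::ridge_solve(crossprod(X), crossprod(X, Y), lambda)
  oracle <- solve(crossprod(X) + lambda * diag(5), crossprod(X, Y))
  expect_equal(as.numeric(got), as.numeric(oracle), tolerance = 1e-8)
  # independent route: numerical minimisation of the penalised loss
  opt <- optim(rep(0, 5), function(b) sum((Y - X %*% b)^2) + lambda * sum(b^2),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(as.numeric(got), opt$par, tolerance = 1e-5)
})

test_that("noiseless full-rank systems are identified as lambda -> 0", {
  set.seed(21)
  X <- matrix(rnorm(200 * 4), 200, 4)
  theta <- c(1, -2, 0.3, 4)
  Y <- as.numeric(X %*% theta)
  got <- ramptime:::ridge_solve(crossprod(X), crossprod(X, Y), 1e-10)
  expect_equal(as.numeric(got), theta, tolerance = 1e-6)
})

test_that("nuisance discretisation finds planted bursts and nothing else", {
  fs <- 200
  expect_length(discretize_nuisance_events(numeric(2000), fs), 0)
  x <- rnorm(4000, sd = 0.05)
  onsets <- c(5, 10, 15)
  for (o in onsets) {
    idx <- round(o * fs) + 1:20
    x[idx] <- x[idx] + 3
  }
  ev <- discretize_nuisance_events(x, fs)
  expect_length(ev, 3)
  expect_true(all(abs(ev - onsets) <= 2 / fs))
  # unreachable threshold
  expect_length(discretize_nuisance_events(x, fs, k = 1000), 0)
})

test_that("stretch predictors tile the cue-to-lick interval proportionally", {
  gp <- generative_params(n_trials = 6, noise_sd = 0.1)
  cfg <- task_config(sampling_rate = 200)
  trials <- build_trial_timeline(c(2, 4, 3, 2.5, 3.5, 4.5), cfg, seed = 30)
  s <- synthesize_session(trials, gp, cfg, seed = 31)
  d <- session_dff_raw <- s$channels$gcamp
  des <- build_design_matrix(s, d, nest_level = 5, fit_rate = 100,
                             n_stretch = 100)
  S <- des$X[, des$groups == "stretch", drop = FALSE]
  sc <- des$scale[des$groups == "stretch"]
  S <- S %*% Matrix::Diagonal(x = sc)    # undo max-abs scaling
  for (tr_id in c(1, 2)) {               # licks at 2 s and 4 s
    rows <- des$trial == tr_id
    per_pred <- Matrix::colSums(S[rows, , drop = FALSE])
    active <- sum(per_pred)
    expect_true(all(abs(per_pred - active / 100) <= 1.1))
  }
  # trials with move times 2 and 4 s: active windows scale with the interval
  n1 <- sum(des$X[des$trial == 1, des$groups == "stretch"] != 0)
  n2 <- sum(des$X[des$trial == 2, des$groups == "stretch"] != 0)
  expect_equal(n2 / n1, 2, tolerance = 0.05)

  # nest-4 offset column is proportional to the trial's first-lick time
  off <- des$X[, des$groups == "offset"] * des$scale[des$groups == "offset"]
  o1 <- unique(off[des$trial == 1])
  o2 <- unique(off[des$trial == 2])
  expect_equal(o2 / o1, 2, tolerance = 1e-9)
})

test_that("predictor rescaling leaves fitted predictions unchanged", {
  s <- ramp_session_250()
  d <- session_dff(s)
  ctl <- session_dff(s, "control")
  des1 <- build_design_matrix(s, d, nest_level = 1, control_dff = ctl)
  des2 <- build_design_matrix(s, d, nest_level = 1,
                              control_dff = structure(as.numeric(ctl) * 7,
                                                      class = "dff_trace"))
  f1 <- fit_nested_ridge(des1, seed = 2)
  f2 <- fit_nested_ridge(des2, seed = 2)
  expect_equal(f1$nests$test_loss, f2$nests$test_loss, tolerance = 1e-10)
})

test_that("coefficient-uncertainty draws match the analytic covariance", {
  set.seed(22)
  n <- 400
  X <- cbind(1, rnorm(n), rnorm(n))
  theta <- c(0.5, 2, -1)
  Y <- as.numeric(X %*% theta) + rnorm(n, sd = 0.3)
  lambda <- 0.01
  fit <- ramptime:::nested_ridge(Y, X, groups = c("x0", "a", "b"),
                                 group_order = c("x0", "a", "b"),
                                 fold_id = seq_len(n), lambdas = lambda,
                                 seed = 1)
  sim <- simulate_fit_uncertainty(fit, n_draws = 4000, seed = 3)
  G <- crossprod(X)
  A <- solve(G + lambda * diag(3))
  th <- fit$coefficients[[3]]
  res <- Y - as.numeric(X %*% th)
  Sig <- (sum(res^2) / (n - 3)) * A %*% G %*% A
  emp <- cov(sim$draws)
  expect_lt(max(abs(emp - Sig)) / max(abs(Sig)), 0.1)
  # bands contain the point prediction everywhere
  expect_true(all(sim$bands$lo <= sim$bands$fit + 1e-9 &
                    sim$bands$fit <= sim$bands$hi + 1e-9))
  # degenerate noise: draws collapse on the estimate
  Y0 <- as.numeric(X %*% theta)
  fit0 <- ramptime:::nested_ridge(Y0, X, groups = c("x0", "a", "b"),
                                  group_order = c("x0", "a", "b"),
                                  fold_id = seq_len(n), lambdas = 1e-8,
                                  seed = 1)
  sim0 <- simulate_fit_uncertainty(fit0, n_draws = 200, seed = 4)
  expect_lt(max(apply(sim0$draws, 2, sd)), 1e-4)
})

test_that("PCA of ramping intervals matches an SVD oracle", {
  iv <- ramp_intervals_100()
  cfg <- task_config()
  # rank-1 input: scalar multiples of one ramp
  base <- seq(0, 1, length.out = 57)
  fake <- iv[1:6, ]
  fake$signal <- lapply(1:6, function(i) i * base)
  fake$valid <- TRUE
  attr(fake, "fs") <- 10
  p1 <- pca_ramping_intervals(fake, task_config(sampling_rate = 10))
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-9)

  # random matrix: variance explained equals the singular-value oracle
  set.seed(23)
  fake2 <- iv[1:8, ]
  fake2$signal <- lapply(1:8, function(i) rnorm(57))
  fake2$valid <- TRUE
  attr(fake2, "fs") <- 10
  p2 <- pca_ramping_intervals(fake2, task_config(sampling_rate = 10))
  M <- t(vapply(fake2$signal, ramptime:::interp_to_length, numeric(57),
                n_out = 57))
  sv <- svd(scale(M, center = TRUE, scale = FALSE))$d
  expect_equal(p2$var_explained, sv^2 / sum(sv^2), tolerance = 1e-8)
})

test_that("ramp sessions concentrate in two components, and shapes are ramps", {
  iv <- ramp_intervals_100()
  p <- pca_ramping_intervals(iv, task_config())
  expect_gte(sum(p$var_explained[1:2]), 0.9)
  expect_equal(p$n_samples, max_ramping_samples(task_config()))
  # reconstructions preserve each trial's original length
  keep <- which(iv$valid)
  expect_equal(lengths(p$reconstructed),
               lengths(iv$signal[keep]))
})

test_that("stretch coefficients rise monotonically on ramp-mode data", {
  s <- ramp_session_250()
  d <- session_dff(s)
  des <- build_design_matrix(s, d, nest_level = 5,
                             control_dff = session_dff(s, "control"))
  fit <- fit_nested_ridge(des, seed = 5)
  st <- fit$coefficients[[7]][grepl("^stretch_", names(fit$coefficients[[7]]))]
  rho <- cor(seq_along(st), as.numeric(st), method = "spearman")
  expect_gt(rho, 0.9)
})
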