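#' Raised-cosine basis kernels
#'
#' Builds a set of raised-cosine bumps tiling a time support, the standard
#' basis for event kernels in point-process/calcium GLMs. Centres are linearly
#' spaced, or log-spaced (denser early) for post-event sets such as the cue
#' response.
#'
#' @param n Number of kernels.
#' @param support Two-element support relative to the event, seconds.
#' @param spacing `"linear"` or `"log"`.
#' @return Function `f(dt)` mapping event-relative times to an
#'   `length(dt) x n` matrix of kernel values (zero off support).
#' @export
raised_cosine_basis <- function(n, support, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  stopifnot(n >= 1, support[2] > support[1])
  if (spacing == "linear") {
    centers <- seq(support[1], support[2], length.out = n)
    width <- if (n > 1) 2 * diff(centers[1:2]) else diff(support)
    warp <- identity
  } else {
    off <- 0.02
    lo <- log(off); hi <- log(support[2] - support[1] + off)
    centers <- seq(lo, hi, length.out = n)
    width <- if (n > 1) 2 * diff(centers[1:2]) else hi - lo
    warp <- function(dt) log(pmax(dt - support[1], 0) + off)
  }
  function(dt) {
    u <- warp(dt)
    out <- vapply(centers, function(c0) {
      v <- 0.5 * (1 + cos(pi * (u - c0) / width))
      v[abs(u - c0) > width | dt < support[1] | dt > support[2]] <- 0
      v
    }, numeric(length(dt)))
    matrix(out, nrow = length(dt), ncol = n)
  }
}

#' Discretise a movement channel into events
#'
#' Thresholds an EMG/accelerometer channel at `k` standard deviations above a
#' rolling (1 s moving-average) baseline, with a refractory period between
#' events. A silent channel yields no events.
#'
#' @param channel Numeric movement trace.
#' @param fs Sampling rate, Hz.
#' @param k SD multiple above the rolling baseline.
#' @param refractory Minimum inter-event interval, seconds.
#' @return Event times in seconds.
#' @export
discretize_nuisance_events <- function(channel, fs, k = 3, refractory = 0.1) {
  sdv <- stats::sd(channel)
  if (sdv == 0) return(numeric(0))
  base <- moving_average_centered(channel, round(0.5 * fs))
  thr <- base + k * sdv
  above <- channel > thr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(onsets)) return(numeric(0))
  keep <- onsets[1]
  for (o in onsets[-1]) {
    if ((o - keep[length(keep)]) / fs >= refractory) keep <- c(keep, o)
  }
  (keep - 1) / fs
}

# predictor-group order defining the nests of the encoding model
encoding_groups <- c("x0", "control", "cue", "lick", "nuisance", "offset", "stretch")

#' Design matrix for the nested encoding model
#'
#' Concatenates the lamp-off-to-first-lick span of every usable trial and
#' builds, at the requested nest level, the predictor groups: a null offset, the
#' control-channel trace, raised-cosine cue kernels (0 to 0.5 s post-cue,
#' log-spaced), first-lick kernels (-0.5 to 0 s, linear), nuisance-movement
#' kernels (-0.5 to +0.5 s around thresholded EMG/accelerometer events), a
#' timing-dependent constant offset spanning lamp-off to lick with amplitude
#' proportional to the trial's first-lick time, and 500 "stretch" indicators
#' each marking one 1/500 fraction of the cue-to-lick interval. Every
#' predictor is scaled to maximum absolute amplitude 1.
#'
#' @param session A `ramp_session`.
#' @param dff Signal-channel dF/F trace (session sampling rate).
#' @param nest_level Integer 0-5; groups up to this nest are included.
#' @param control_dff Control-channel dF/F trace.
#' @param fit_rate Sampling rate used for fitting, Hz.
#' @param n_cue,n_lick,n_nuisance Kernel counts per event set.
#' @param n_stretch Number of stretch indicators.
#' @return List: `X` (sparse timepoints x predictors), `Y`, `groups`
#'   (per-column group tag), `trial` (per-row trial id), `t_rel` (per-row time
#'   from lamp-off), `excluded` trial ids.
#' @export
build_design_matrix <- function(session, dff, nest_level = 5,
                                control_dff = NULL, fit_rate = 100,
                                n_cue = 24, n_lick = 28, n_nuisance = 44,
                                n_stretch = 500) {
  stopifnot(nest_level %in% 0:5)
  fs <- session$config$sampling_rate
  step <- max(1L, round(fs / fit_rate))
  fsf <- fs / step
  tr <- session$trials
  usable <- which(!is.na(tr$first_lick_time) & tr$first_lick_time >= 0.5)
  excluded <- setdiff(seq_len(nrow(tr)), usable)

  nuis_events <- sort(c(
    discretize_nuisance_events(session$channels$emg, fs),
    discretize_nuisance_events(session$channels$accel, fs)
  ))

  x <- as.numeric(dff)
  ctl <- if (is.null(control_dff)) numeric(length(x)) else as.numeric(control_dff)

  rows <- lapply(usable, function(i) {
    i0 <- time_index(tr$lampoff_time[i], fs)
    i1 <- time_index(tr$cue_time[i] + tr$first_lick_time[i], fs)
    idx <- seq(i0, i1, by = step)
    tibble(trial = i, idx = idx,
           t_abs = (idx - 1) / fs,
           cue = tr$cue_time[i],
           lick = tr$cue_time[i] + tr$first_lick_time[i],
           T_i = tr$first_lick_time[i])
  })
  d <- dplyr::bind_rows(rows)
  n <- nrow(d)

  blocks <- list()
  groups <- character(0)
  add_block <- function(m, tag) {
    m <- methods::as(m, "CsparseMatrix")
    blocks[[length(blocks) + 1L]] <<- m
    groups <<- c(groups, rep(tag, ncol(m)))
  }

  add_block(Matrix::Matrix(1, n, 1), "x0")
  if (nest_level >= 1) add_block(Matrix::Matrix(ctl[d$idx], ncol = 1), "control")
  if (nest_level >= 2) {
    cue_b <- raised_cosine_basis(n_cue, c(0, 0.5), "log")
    add_block(Matrix::Matrix(cue_b(d$t_abs - d$cue), sparse = TRUE), "cue")
    lick_b <- raised_cosine_basis(n_lick, c(-0.5, 0), "linear")
    add_block(Matrix::Matrix(lick_b(d$t_abs - d$lick), sparse = TRUE), "lick")
  }
  if (nest_level >= 3) {
    nb <- raised_cosine_basis(n_nuisance, c(-0.5, 0.5), "linear")
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (e in nuis_events) {
      near <- which(abs(d$t_abs - e) <= 0.5)
      if (length(near)) {
        B <- nb(d$t_abs[near] - e)
        nz <- which(B != 0, arr.ind = TRUE)
        ii <- c(ii, near[nz[, 1]])
        jj <- c(jj, nz[, 2])
        xx <- c(xx, B[nz])
      }
    }
    acc <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(n, n_nuisance))
    add_block(acc, "nuisance")
  }
  if (nest_level >= 4) add_block(Matrix::Matrix(d$T_i, ncol = 1), "offset")
  if (nest_level >= 5) {
    frac <- (d$t_abs - d$cue) / (d$lick - d$cue)
    inwin <- frac >= 0 & frac <= 1
    bin <- pmin(n_stretch, floor(frac[inwin] * n_stretch) + 1L)
    S <- Matrix::sparseMatrix(i = which(inwin), j = bin, x = 1,
                              dims = c(n, n_stretch))
    add_block(S, "stretch")
  }

  X <- do.call(cbind, blocks)
  sc <- col_abs_max(X)
  sc[sc == 0] <- 1
  X <- X %*% Matrix::Diagonal(x = 1 / sc)
  list(X = X, Y = x[d$idx], groups = groups, trial = d$trial,
       t_rel = d$t_abs - (tr$lampoff_time[d$trial]),
       fit_rate = fsf, excluded = excluded, scale = sc,
       nuisance_events = nuis_events)
}

# per-column maximum absolute value without densifying
col_abs_max <- function(X) {
  X <- methods::as(X, "CsparseMatrix")
  p <- X@p
  vapply(seq_len(ncol(X)), function(j) {
    if (p[j + 1] == p[j]) 0 else max(abs(X@x[(p[j] + 1):p[j + 1]]))
  }, numeric(1))
}

# closed-form ridge on the Gram matrix; penalty convention
# theta = (X'X + lambda I)^-1 X'Y
ridge_solve <- function(G, b, lambda) {
  d <- nrow(G)
  solve(G + lambda * diag(d), b)
}

# shared nested ridge/CV engine; X dense or sparse (rows = observations),
# groups orders the nests, fold_id blocks CV by trial
nested_ridge <- function(Y, X, groups, group_order, fold_id, folds = 5,
                         lambdas = 10^seq(-3, 3, length.out = 13),
                         seed = NULL) {
  seed_rng(seed)
  un <- unique(fold_id)
  fold_of <- sample(rep(seq_len(folds), length.out = length(un)))
  names(fold_of) <- as.character(un)
  obs_fold <- fold_of[as.character(fold_id)]

  nests <- group_order[group_order %in% unique(groups)]
  results <- list()
  coefs <- list()
  prev_mse <- NULL
  for (j in seq_along(nests)) {
    cols <- which(groups %in% nests[seq_len(j)])
    Xj <- X[, cols, drop = FALSE]
    d <- length(cols)
    cv_pen <- matrix(NA_real_, folds, length(lambdas))
    cv_mse <- matrix(NA_real_, folds, length(lambdas))
    for (f in seq_len(folds)) {
      tr <- obs_fold != f
      Xtr <- Xj[tr, , drop = FALSE]; Ytr <- Y[tr]
      Xte <- Xj[!tr, , drop = FALSE]; Yte <- Y[!tr]
      G <- as.matrix(Matrix::crossprod(Xtr))
      b <- as.numeric(Matrix::crossprod(Xtr, Ytr))
      for (l in seq_along(lambdas)) {
        th <- ridge_solve(G, b, lambdas[l])
        res <- Yte - as.numeric(Xte %*% th)
        cv_mse[f, l] <- mean(res^2)
        cv_pen[f, l] <- cv_mse[f, l] + lambdas[l] * sum(th^2)
      }
    }
    l_star <- which.min(colMeans(cv_pen))
    lambda_star <- lambdas[l_star]
    G <- as.matrix(Matrix::crossprod(Xj))
    b <- as.numeric(Matrix::crossprod(Xj, Y))
    th <- ridge_solve(G, b, lambda_star)
    fitted <- as.numeric(Xj %*% th)
    res <- Y - fitted
    n <- length(Y)
    mse_train <- mean(res^2)
    mse_test <- colMeans(cv_mse)[l_star]
    r2 <- 1 - sum(res^2) / sum((Y - mean(Y))^2)
    results[[j]] <- tibble(
      nest = j - 1L, input = nests[j], n_predictors = d,
      lambda = lambda_star,
      train_loss = mse_train,
      test_loss = mse_test,
      test_loss_penalized = colMeans(cv_pen)[l_star],
      r_squared = r2,
      aic = n * log(mse_train) + 2 * d,
      bic = n * log(mse_train) + log(n) * d,
      loss_improvement = if (is.null(prev_mse)) NA_real_
                         else (prev_mse - mse_test) / prev_mse
    )
    coefs[[j]] <- stats::setNames(as.numeric(th), paste0(
      groups[cols], "_", stats::ave(cols, groups[cols], FUN = seq_along)))
    prev_mse <- mse_test
  }
  structure(
    list(nests = dplyr::bind_rows(results), coefficients = coefs,
         groups = groups, group_order = nests, Y = Y, X = X,
         obs_fold = obs_fold),
    class = "nested_fit"
  )
}

#' Fit the nested encoding model
#'
#' Fits the signal-channel dF/F as a ridge-regularised linear function of the
#' design-matrix nests (null offset, control channel, cue + lick kernels,
#' nuisance kernels, timing-dependent baseline offset, stretch), with the
#' regularisation weight of each nest chosen by five-fold cross-validation
#' blocked by trial. Reports, per nest, training and held-out losses, AIC/BIC,
#' R-squared, and the relative held-out loss improvement over the previous
#' nest.
#'
#' @param design Output of [build_design_matrix()].
#' @param folds CV folds.
#' @param lambdas Ridge penalty grid.
#' @param seed Seed for the fold assignment.
#' @return A `nested_fit`: `$nests` ledger tibble plus per-nest coefficients.
#' @export
fit_nested_ridge <- function(design, folds = 5,
                             lambdas = 10^seq(-3, 3, length.out = 13),
                             seed = 1) {
  nested_ridge(design$Y, design$X, design$groups, encoding_groups,
               fold_id = design$trial, folds = folds, lambdas = lambdas,
               seed = seed)
}

#' @export
print.nested_fit <- function(x, ...) {
  cat("<nested_fit>\n")
  print(x$nests)
  invisible(x)
}

#' Simulate coefficient uncertainty of a ridge fit
#'
#' Redraws coefficients from the Gaussian sampling distribution of the final
#' (or requested) nest's ridge estimator, using the sandwich covariance
#' `sigma2 * A^-1 G A^-1` with `A = G + lambda I`, `G = X'X`, and `sigma2` the
#' training residual variance. Optionally evaluates prediction bands from a
#' subset of coefficient draws.
#'
#' @param fit A `nested_fit`.
#' @param nest Nest index (0-based; default last).
#' @param n_draws Number of coefficient draws.
#' @param n_sim Number of draws used for the prediction band.
#' @param seed Seed.
#' @return List: `draws` (n_draws x d), `bands` tibble (`t_index`, `fit`,
#'   `lo`, `hi`).
#' @export
simulate_fit_uncertainty <- function(fit, nest = NULL, n_draws = 1000,
                                     n_sim = 300, seed = 1) {
  seed_rng(seed)
  j <- if (is.null(nest)) length(fit$coefficients) else nest + 1L
  cols <- which(fit$groups %in% fit$group_order[seq_len(j)])
  Xj <- fit$X[, cols, drop = FALSE]
  th <- fit$coefficients[[j]]
  lambda <- fit$nests$lambda[j]
  G <- as.matrix(Matrix::crossprod(Xj))
  A_inv <- solve(G + lambda * diag(length(th)))
  res <- fit$Y - as.numeric(Xj %*% th)
  sigma2 <- sum(res^2) / max(1, length(res) - length(th))
  Sig <- sigma2 * A_inv %*% G %*% A_inv
  ch <- tryCatch(chol(Sig), error = function(e) {
    warn("singular coefficient covariance; jittering")
    chol(Sig + diag(1e-10 * max(diag(Sig)) + 1e-300, nrow(Sig)))
  })
  Z <- matrix(stats::rnorm(n_draws * length(th)), n_draws)
  draws <- sweep(Z %*% ch, 2, th, "+")
  sim <- draws[seq_len(min(n_sim, n_draws)), , drop = FALSE]
  pred <- as.matrix(Xj %*% t(sim))
  bands <- tibble(
    t_index = seq_len(nrow(pred)),
    fit = as.numeric(Xj %*% th),
    lo = apply(pred, 1, stats::quantile, 0.025),
    hi = apply(pred, 1, stats::quantile, 0.975)
  )
  list(draws = draws, bands = bands, sigma2 = sigma2)
}

#' Maximum ramping-interval length in samples
#'
#' The longest possible ramping interval given the task structure: the trial
#' duration minus the 0.7 s post-cue buffer and the 0.6 s pre-lick buffer,
#' expressed in samples at the session sampling rate (5,700 samples for the
#' 3.3-s task at 1 kHz).
#'
#' @param cfg A [task_config()].
#' @param cue_buffer,lick_buffer Buffers excluded from the interval, seconds.
#' @return Integer number of samples.
#' @export
#' @examples
#' max_ramping_samples(task_config())
max_ramping_samples <- function(cfg = task_config(), cue_buffer = 0.7,
                                lick_buffer = 0.6) {
  as.integer(round((cfg$trial_end - cue_buffer - lick_buffer) *
                     cfg$sampling_rate))
}

#' PCA of ramping intervals
#'
#' Linearly interpolates each trial's ramping interval (cue + 0.7 s to first
#' lick - 0.6 s) to the maximum ramping-interval length, runs PCA across
#' trials, and reconstructs each trial from the first `n_pc` components,
#' down-sampled back to its original duration. Intervals shorter than 0.1 s
#' are excluded.
#'
#' @param intervals A [ramping_intervals()] tibble.
#' @param cfg A [task_config()] (sets the interpolation length).
#' @param n_pc Components kept in the reconstruction.
#' @return List: `var_explained` (per PC), `scores`, `rotation`,
#'   `reconstructed` (list of per-trial traces at original lengths), `trials`
#'   (ids kept), `n_samples` interpolation length.
#' @export
pca_ramping_intervals <- function(intervals, cfg = task_config(), n_pc = 3) {
  keep <- intervals$valid
  if (sum(keep) < 3) abort("fewer than 3 usable trials after exclusion")
  sigs <- intervals$signal[keep]
  n_samp <- max_ramping_samples(cfg)
  M <- t(vapply(sigs, interp_to_length, numeric(n_samp), n_out = n_samp))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_pc, ncol(pc$rotation))
  recon_full <- pc$x[, seq_len(k), drop = FALSE] %*%
    t(pc$rotation[, seq_len(k), drop = FALSE])
  recon_full <- sweep(recon_full, 2, pc$center, "+")
  recon <- lapply(seq_along(sigs), function(i) {
    interp_to_length(recon_full[i, ], length(sigs[[i]]))
  })
  list(var_explained = ve, scores = pc$x, rotation = pc$rotation,
       reconstructed = recon, trials = intervals$trial[keep],
       n_samples = n_samp)
}
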