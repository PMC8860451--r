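# ---- probabilistic movement-state decoding ----------------------------------

state_history_bins <- rbind(
  c(1.8, 2.0), c(1.6, 1.8), c(1.4, 1.6), c(1.2, 1.4), c(1.0, 1.2),
  c(0.8, 1.0), c(0.6, 0.8), c(0.4, 0.6), c(0.2, 0.4)
)
state_nest_names <- c(paste0("hist_", sprintf("%.1f_%.1f",
                                              state_history_bins[, 1],
                                              state_history_bins[, 2])),
                      "current")

#' Build the movement-state series and history design
#'
#' Downsamples the smoothed signal to `fs_out` (100 Hz) and labels, per licked
#' trial, every timepoint from the cue up to 160 ms before the first lick as
#' the non-movement state (0) and the single timepoint 150 ms before the first
#' lick as the movement state (1); later points are excluded. Predictors are
#' the current signal value and nine 200-ms mean history bins reaching 2 s
#' into the past (most distant first, matching the nesting order). History
#' bins extending before the cue are zeroed and flagged by a mask indicator.
#'
#' @param session A `ramp_session`.
#' @param dff Signal trace at the session rate.
#' @param fs_out Output rate, Hz.
#' @param smooth_sigma Gaussian smoothing SD, seconds.
#' @param drop_short Drop timepoints with incomplete history instead of
#'   masking.
#' @return Tibble: `trial`, `t` (seconds post-cue), `state`, `mask`, then the
#'   nine history bins (distant first) and `current`.
#' @export
build_state_series <- function(session, dff, fs_out = 100,
                               smooth_sigma = 0.1, drop_short = FALSE) {
  fs <- session$config$sampling_rate
  x <- as.numeric(dff)
  if (smooth_sigma > 0) x <- gaussian_smooth(x, smooth_sigma, fs)
  step <- max(1L, round(fs / fs_out))
  xd <- x[seq(1L, length(x), by = step)]
  fsd <- fs / step
  tr <- session$trials
  licked <- which(!is.na(tr$first_lick_time) & tr$first_lick_time > 0.2)
  if (!length(licked)) abort("no licked trials")
  rows <- lapply(licked, function(i) {
    cue <- tr$cue_time[i]
    lick <- cue + tr$first_lick_time[i]
    t1 <- lick - 0.15                      # movement-state point
    t0_last <- lick - 0.16                 # last non-movement point
    tt <- c(seq(cue, t0_last, by = 1 / fsd), t1)
    st <- c(rep(0L, length(tt) - 1L), 1L)
    idx <- time_index(tt, fsd)
    cur <- xd[idx]
    hist <- matrix(0, length(tt), nrow(state_history_bins))
    mask <- numeric(length(tt))
    cs <- c(0, cumsum(xd))
    cue_i <- time_index(cue, fsd)
    for (b in seq_len(nrow(state_history_bins))) {
      lo <- idx - round(state_history_bins[b, 2] * fsd)
      hi <- idx - round(state_history_bins[b, 1] * fsd)
      lo2 <- pmax(lo, cue_i)
      ok <- hi >= lo2
      v <- numeric(length(tt))
      v[ok] <- (cs[hi[ok] + 1L] - cs[lo2[ok]]) / (hi[ok] - lo2[ok] + 1L)
      mask[lo < cue_i] <- 1
      hist[, b] <- v
    }
    out <- tibble(trial = i, t = tt - cue, state = st, mask = mask)
    colnames(hist) <- state_nest_names[seq_len(ncol(hist))]
    dplyr::bind_cols(out, as_tibble(hist), tibble(current = cur))
  })
  out <- dplyr::bind_rows(rows)
  if (drop_short) out <- out[out$mask == 0, ]
  new_ramptime_result(out, "state_series")
}

fit_logistic <- function(X, y, ridge = 1e-3) {
  # ridge-stabilised IRLS logistic; the tiny penalty guards against
  # separation and against coefficient blow-up when smooth signals make the
  # history bins nearly collinear
  d <- ncol(X)
  beta <- numeric(d)
  for (it in 1:50) {
    eta <- as.numeric(X %*% beta)
    p <- inv_logit(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X * w, X) + ridge * diag(d)
    beta_new <- solve(H, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' Fit the nested movement-state model
#'
#' For each nest (history bins added most-distant first, then the current
#' signal value), fits a logistic regression of movement state on the signal
#' predictors. Class balance is enforced by down-sampling the non-movement
#' points to the movement-point count; each nest is refit on `n_boot` random
#' down-sampled sets and the coefficients averaged, with their refit-to-refit
#' SD reported.
#'
#' @param series A [build_state_series()] tibble.
#' @param n_boot Number of balanced refits.
#' @param nests Which nests to fit (default all 10).
#' @param seed Seed.
#' @return List of class `state_fit`: `coefficients` tibble (`nest`, `term`,
#'   `estimate`, `sd`), `series` reference, `nest_terms`.
#' @export
fit_state_model <- function(series, n_boot = 100, nests = NULL, seed = 1) {
  seed_rng(seed)
  nests <- nests %||% seq_along(state_nest_names)
  ones <- which(series$state == 1L)
  zeros <- which(series$state == 0L)
  n1 <- length(ones)
  if (n1 < 10) abort("too few movement-state points")
  out <- list()
  for (j in nests) {
    terms <- c("(Intercept)", "mask", state_nest_names[seq_len(j)])
    cols <- c("mask", state_nest_names[seq_len(j)])
    B <- matrix(NA_real_, n_boot, length(terms))
    for (b in seq_len(n_boot)) {
      sel <- c(ones, sample(zeros, min(n1, length(zeros))))
      X <- cbind(1, as.matrix(series[sel, cols]))
      B[b, ] <- fit_logistic(X, series$state[sel])
    }
    out[[length(out) + 1L]] <- tibble(
      nest = j, term = terms,
      estimate = colMeans(B),
      sd = apply(B, 2, stats::sd)
    )
  }
  structure(
    list(coefficients = dplyr::bind_rows(out), series = series,
         nest_terms = state_nest_names, n_boot = n_boot),
    class = "state_fit"
  )
}

#' Fitted hazard from the movement-state model
#'
#' Evaluates the averaged logistic model at every timepoint, averages the
#' predicted movement probability across trials within time bins from the
#' cue, min-max normalises both this fitted hazard and the empirical hazard
#' of the session's first-lick distribution, and reports the R-squared
#' (squared correlation) between them over defined bins. Because the model is
#' trained on class-balanced subsamples, predicted probabilities are inflated
#' by the down-sampling prior; by default the standard case-control intercept
#' correction (`- log(n0/n1)`) is applied before binning so the fitted curve
#' lives on the true hazard scale (`balance_correction = FALSE` reproduces
#' the plain rescale-by-normalisation convention). Bins whose empirical
#' hazard rests on fewer than `min_opportunities` remaining opportunities are
#' masked from the comparison.
#'
#' @param fit A [fit_state_model()] result.
#' @param nest Nest whose coefficients to use (default: highest fitted).
#' @param bin_width Hazard bin width, seconds.
#' @param balance_correction Apply the case-control intercept correction.
#' @param min_opportunities Opportunity floor for empirical-hazard bins.
#' @return List of class `fitted_hazard`: `curves` tibble (`bin_center`,
#'   `fitted`, `empirical`, plus normalised versions), `r_squared`.
#' @export
fitted_hazard <- function(fit, nest = NULL, bin_width = 0.25,
                          balance_correction = TRUE, min_opportunities = 10) {
  series <- fit$series
  nest <- nest %||% max(fit$coefficients$nest)
  co <- fit$coefficients[fit$coefficients$nest == nest, ]
  cols <- c("mask", fit$nest_terms[seq_len(nest)])
  X <- cbind(1, as.matrix(series[, cols]))
  off <- if (balance_correction) {
    log(sum(series$state == 0) / sum(series$state == 1))
  } else {
    0
  }
  p <- inv_logit(as.numeric(X %*% co$estimate) - off)
  hazard_comparison(series, p, bin_width, min_opportunities, nest)
}

# shared binning/comparison step: predicted per-timepoint movement
# probabilities vs the empirical hazard of the same trials' first licks
hazard_comparison <- function(series, p, bin_width, min_opportunities, nest) {
  d <- tibble(t = series$t, p = p, state = series$state)
  d$bin <- floor(d$t / bin_width)
  fitted_curve <- d |> dplyr::group_by(bin) |>
    dplyr::summarise(fitted = mean(.data$p), .groups = "drop")
  # empirical hazard from the same trials' first-lick distribution
  licks <- series |> dplyr::filter(.data$state == 1L) |>
    dplyr::mutate(lick = .data$t + 0.15)
  hz <- hazard_function(timing_histogram(licks$lick, bin_width = bin_width))
  emp <- tibble(bin = floor((hz$bin_center - bin_width / 2) / bin_width + 0.5),
                empirical = hz$hazard, opportunities = hz$opportunities)
  curves <- dplyr::inner_join(fitted_curve, emp, by = "bin") |>
    dplyr::filter(!is.na(.data$empirical),
                  .data$opportunities >= min_opportunities)
  curves$bin_center <- (curves$bin + 0.5) * bin_width
  curves$fitted_norm <- minmax_scale(curves$fitted)
  curves$empirical_norm <- minmax_scale(curves$empirical)
  # opportunity-weighted squared correlation: bins estimated from many
  # remaining trials count proportionally more, which keeps the tail bins
  # (few trials, high sampling noise in both curves) from dominating
  r2 <- if (nrow(curves) > 2 && !anyNA(curves$fitted_norm) &&
            !anyNA(curves$empirical_norm)) {
    w <- curves$opportunities
    f <- curves$fitted
    e <- curves$empirical
    mf <- stats::weighted.mean(f, w)
    me <- stats::weighted.mean(e, w)
    (sum(w * (f - mf) * (e - me)) /
       sqrt(sum(w * (f - mf)^2) * sum(w * (e - me)^2)))^2
  } else {
    NA_real_
  }
  r2_sse <- if (nrow(curves) > 2) {
    1 - sum((curves$empirical - curves$fitted)^2) /
      sum((curves$empirical - mean(curves$empirical))^2)
  } else {
    NA_real_
  }
  structure(list(curves = curves, r_squared = r2, r_squared_sse = r2_sse,
                 nest = nest),
            class = "fitted_hazard")
}

#' Cross-validated fitted hazard
#'
#' Trial-blocked K-fold variant of [fitted_hazard()]: the balanced logistic
#' model is refit with each fold's trials held out and predictions for every
#' timepoint come from the fold that excluded its trial, so the fitted hazard
#' is fully out-of-sample. This removes the in-sample optimism that would
#' otherwise let a label-shuffled control retain spurious hazard structure.
#'
#' @param series A [build_state_series()] tibble.
#' @param folds Number of trial-blocked folds.
#' @param n_boot Balanced refits per fold.
#' @param nest Nest evaluated (default full model).
#' @param bin_width Hazard bin width, seconds.
#' @param balance_correction,min_opportunities As in [fitted_hazard()].
#' @param seed Seed.
#' @return A `fitted_hazard`.
#' @export
cv_fitted_hazard <- function(series, folds = 5, n_boot = 50, nest = NULL,
                             bin_width = 0.25, balance_correction = TRUE,
                             min_opportunities = 10, seed = 1) {
  seed_rng(seed)
  nest <- nest %||% length(state_nest_names)
  trials <- unique(series$trial)
  fold_of <- sample(rep(seq_len(folds), length.out = length(trials)))
  names(fold_of) <- as.character(trials)
  obs_fold <- fold_of[as.character(series$trial)]
  off <- if (balance_correction) {
    log(sum(series$state == 0) / sum(series$state == 1))
  } else {
    0
  }
  cols <- c("mask", state_nest_names[seq_len(nest)])
  p <- numeric(nrow(series))
  for (f in seq_len(folds)) {
    train <- series[obs_fold != f, ]
    fit <- fit_state_model(train, n_boot = n_boot, nests = nest,
                           seed = seed + f)
    co <- fit$coefficients[fit$coefficients$nest == nest, ]
    X <- cbind(1, as.matrix(series[obs_fold == f, cols]))
    p[obs_fold == f] <- inv_logit(as.numeric(X %*% co$estimate) - off)
  }
  hazard_comparison(series, p, bin_width, min_opportunities, nest)
}

#' Shuffle control for the state model
#'
#' Refits the movement-state model after shuffling the state labels across
#' timepoints, erasing any real association between signal and state, and
#' returns the shuffled fitted-hazard R-squared. A large drop relative to the
#' unshuffled fit guards against overfitting.
#'
#' @param series A [build_state_series()] tibble.
#' @param n_boot Balanced refits.
#' @param nest Nest evaluated.
#' @param seed Seed.
#' @return A `fitted_hazard` for the shuffled fit.
#' @export
shuffled_state_fit <- function(series, n_boot = 100, nest = NULL, seed = 1) {
  seed_rng(seed)
  shuffled <- series
  perm <- sample.int(nrow(series))
  cols <- intersect(c("mask", state_nest_names, "current"), colnames(series))
  shuffled[, cols] <- series[perm, cols]
  cv_fitted_hazard(shuffled, n_boot = n_boot, nest = nest, seed = seed)
}

#' Time-slice model selection
#'
#' Compares candidate predictor sets (signal only, previous-trial history
#' only, or both) by summed BIC over 500-ms time slices from the cue. Within
#' each slice every trial contributes at most one point: its mean signal over
#' the slice, with state 1 only if its movement point falls inside the slice;
#' trials exit after their lick. Slices with too few points of either class
#' are reported as non-converging and excluded from the sum.
#'
#' @param session A `ramp_session`.
#' @param dff Signal trace.
#' @param window Slice width, seconds.
#' @param fs_out Downsampled rate, Hz.
#' @param min_per_class Minimum points per class for a slice to be fit.
#' @return Tibble of class `slice_bic`: `model`, `bic`, `n_slices`, `winner`.
#' @export
time_slice_selection <- function(session, dff, window = 0.5, fs_out = 100,
                                 min_per_class = 3) {
  tr <- session$trials
  series <- build_state_series(session, dff, fs_out = fs_out)
  prev <- function(v) c(NA, v[-length(v)])
  hist1 <- prev(tr$first_lick_time)
  hist1[is.na(hist1)] <- mean(tr$first_lick_time, na.rm = TRUE)
  out1 <- as.numeric(prev(as.character(tr$outcome)) %in% "reward")
  slices <- split(series, floor(series$t / window))
  models <- list(
    signal = "sig",
    history = c("h1", "o1"),
    signal_history = c("sig", "h1", "o1")
  )
  bics <- stats::setNames(numeric(length(models)), names(models))
  counts <- stats::setNames(integer(length(models)), names(models))
  any_converged <- FALSE
  for (sl in slices) {
    per_trial <- sl |> dplyr::group_by(trial) |>
      dplyr::summarise(sig = mean(.data$current),
                       state = max(.data$state), .groups = "drop")
    per_trial$h1 <- hist1[per_trial$trial]
    per_trial$o1 <- out1[per_trial$trial]
    if (sum(per_trial$state == 1) < min_per_class ||
        sum(per_trial$state == 0) < min_per_class) next
    any_converged <- TRUE
    for (m in names(models)) {
      X <- cbind(1, as.matrix(per_trial[models[[m]]]))
      beta <- fit_logistic(X, per_trial$state)
      p <- inv_logit(as.numeric(X %*% beta))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(per_trial$state * log(p) + (1 - per_trial$state) * log(1 - p))
      bics[m] <- bics[m] - 2 * ll + log(nrow(per_trial)) * ncol(X)
      counts[m] <- counts[m] + 1L
    }
  }
  if (!any_converged) abort("no time slice had enough trials to fit")
  out <- tibble(model = names(models), bic = unname(bics),
                n_slices = unname(counts))
  out$winner <- out$bic == min(out$bic)
  new_ramptime_result(out, "slice_bic")
}
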