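# ---- single-trial ramp-vs-step classification -------------------------------
#
# Signals are min-max normalised per trial before inference so the Beta prior
# on the noise SD lives on (0, 1). Hypotheses are proposed from data-driven
# heuristics (RANSAC line fits for ramps, derivative peaks for steps), scored
# by log prior + iid Gaussian log likelihood of the residuals, and refined by
# retain-the-best importance resampling.

beta_from_mode <- function(mode, nu = 10) {
  mode <- min(max(mode, 1e-3), 1 - 1e-3)
  a <- mode * (nu - 2) + 1
  c(a = a, b = nu - a)
}

# pool of RANSAC consensus line fits: minimal 2-point samples refined on their
# inlier sets, inlier band = 2x the median absolute residual of the current
# consensus (re-estimated per candidate)
ransac_pool <- function(t, y, n_candidates = 50) {
  n <- length(y)
  out <- matrix(NA_real_, n_candidates, 2,
                dimnames = list(NULL, c("slope", "intercept")))
  if (stats::sd(y) == 0) {
    out[, 1] <- 0
    out[, 2] <- y[1]
    return(out)
  }
  for (k in seq_len(n_candidates)) {
    ij <- sample.int(n, 2)
    dt <- t[ij[2]] - t[ij[1]]
    a <- if (dt == 0) 0 else (y[ij[2]] - y[ij[1]]) / dt
    b <- y[ij[1]] - a * t[ij[1]]
    res <- abs(y - (a * t + b))
    band <- 2 * stats::median(res)
    inl <- res <= max(band, 1e-12)
    if (sum(inl) >= 3) {
      fit <- stats::lm.fit(cbind(1, t[inl]), y[inl])
      b <- fit$coefficients[1]
      a <- fit$coefficients[2]
    }
    out[k, ] <- c(a, b)
  }
  out
}

# per-trial proposal context computed once
trial_context <- function(y, fs) {
  n <- length(y)
  t <- (seq_len(n) - 1) / fs
  dur <- max(t[n], 1 / fs)
  maxslope <- (max(y) - min(y)) / dur
  b_max <- mean(y) - maxslope * mean(t)   # intercept at the maximal slope
  # proposal/prior spreads, floored so neither density degenerates when the
  # maxslope intercept happens to pass near the origin
  slope_sd <- max(maxslope, 0.1)
  inter_sd <- max(abs(b_max), 0.1)
  dy <- diff(y)
  if (max(dy) == min(dy)) {
    hi <- 2:(n - 1)                      # flat derivative: all interior points
  } else {
    cand <- which(dy > stats::quantile(dy, 0.95))
    if (!length(cand)) cand <- which(dy == max(dy))
    hi <- cand + 1L                      # step lands after the sharp rise
    hi <- hi[hi > 1 & hi < n]
    if (!length(hi)) hi <- 2:(n - 1)
  }
  list(t = t, y = y, n = n, maxslope = maxslope, b_max = b_max,
       slope_sd = slope_sd, inter_sd = inter_sd,
       sd_y = stats::sd(y), step_idx = hi,
       pool = ransac_pool(t, y))
}

#' Propose a ramp hypothesis
#'
#' Draws a slope/intercept/noise parameterisation for the linear-ramp model of
#' one normalised trial signal: slope is Gaussian around a RANSAC-sampled
#' consensus slope with spread `maxslope` (the largest slope the data
#' supports, range over duration), intercept is Gaussian around the RANSAC
#' intercept with spread `b_max` (the least-squares intercept at `maxslope`),
#' and the noise SD is Beta-distributed with mode equal to the signal SD.
#'
#' @param signal Min-max normalised trial signal.
#' @param fs Interval sampling rate, Hz.
#' @param seed Optional seed.
#' @return List: `class = "ramp"`, `slope`, `intercept`, `sigma`.
#' @export
propose_ramp <- function(signal, fs = 100, seed = NULL) {
  seed_rng(seed)
  ctx <- trial_context(signal, fs)
  propose_ramp_ctx(ctx)
}

propose_ramp_ctx <- function(ctx) {
  k <- sample.int(nrow(ctx$pool), 1)
  ab <- beta_from_mode(ctx$sd_y)
  list(
    class = "ramp",
    slope = stats::rnorm(1, ctx$pool[k, 1], ctx$slope_sd),
    intercept = stats::rnorm(1, ctx$pool[k, 2], ctx$inter_sd),
    sigma = stats::rbeta(1, ab["a"], ab["b"])
  )
}

#' Propose a step hypothesis
#'
#' Draws a step time uniformly from the timepoints whose signal derivative is
#' in the top 5% (all interior points when the derivative is flat), then
#' Gaussian left/right segment amplitudes around the segment means with the
#' segment SDs as spread, and a Beta noise SD with mode equal to the SD of the
#' signal left of the step.
#'
#' @inheritParams propose_ramp
#' @return List: `class = "step"`, `steptime` (seconds), `left`, `right`,
#'   `sigma`.
#' @export
propose_step <- function(signal, fs = 100, seed = NULL) {
  seed_rng(seed)
  ctx <- trial_context(signal, fs)
  propose_step_ctx(ctx)
}

propose_step_ctx <- function(ctx) {
  i <- ctx$step_idx[sample.int(length(ctx$step_idx), 1)]
  yl <- ctx$y[seq_len(i - 1L)]
  yr <- ctx$y[i:ctx$n]
  sdl <- max(stats::sd(yl), 1e-3)
  sdr <- max(stats::sd(yr), 1e-3)
  if (is.na(sdl)) sdl <- 1e-3
  if (is.na(sdr)) sdr <- 1e-3
  ab <- beta_from_mode(if (length(yl) > 1) stats::sd(yl) else ctx$sd_y)
  list(
    class = "step",
    steptime = ctx$t[i],
    left = stats::rnorm(1, mean(yl), sdl),
    right = stats::rnorm(1, mean(yr), sdr),
    sigma = stats::rbeta(1, ab["a"], ab["b"])
  )
}

#' Log joint score of a hypothesis
#'
#' Log proposal-prior density of the hypothesis parameters plus the iid
#' Gaussian log likelihood of the residuals with SD `sigma`. Hypotheses with
#' non-positive `sigma` score `-Inf`.
#'
#' @param signal Normalised trial signal.
#' @param hypothesis A [propose_ramp()] / [propose_step()] hypothesis.
#' @param fs Sampling rate of the interval, Hz.
#' @return Log joint density (scalar).
#' @export
score_hypothesis <- function(signal, hypothesis, fs = 100) {
  ctx <- trial_context(signal, fs)
  score_hypothesis_ctx(ctx, hypothesis)
}

score_hypothesis_ctx <- function(ctx, h) {
  if (h$sigma <= 0 || h$sigma >= 1) return(-Inf)
  if (h$class == "ramp") {
    mu <- h$slope * ctx$t + h$intercept
    ab <- beta_from_mode(ctx$sd_y)
    lp <- stats::dnorm(h$slope, 0, ctx$slope_sd, log = TRUE) +
      stats::dnorm(h$intercept, mean(ctx$y), 1, log = TRUE) +
      stats::dbeta(h$sigma, ab["a"], ab["b"], log = TRUE)
  } else {
    i <- max(2L, min(ctx$n, round(h$steptime * (ctx$n - 1) / ctx$t[ctx$n]) + 1L))
    mu <- ifelse(ctx$t < h$steptime, h$left, h$right)
    ab <- beta_from_mode(ctx$sd_y)
    lp <- -log(length(ctx$step_idx)) +
      stats::dnorm(h$left, mean(ctx$y), 1, log = TRUE) +
      stats::dnorm(h$right, mean(ctx$y), 1, log = TRUE) +
      stats::dbeta(h$sigma, ab["a"], ab["b"], log = TRUE)
  }
  lp + sum(stats::dnorm(ctx$y - mu, 0, h$sigma, log = TRUE))
}

# vectorised scoring of many ramp / step proposals for one trial; returns the
# per-proposal log joint
score_ramps <- function(ctx, slope, intercept, sigma) {
  M <- outer(ctx$t, slope) + rep(intercept, each = ctx$n)
  R <- ctx$y - M
  ll <- -ctx$n * log(sigma * sqrt(2 * pi)) -
    colSums(R^2) / (2 * sigma^2)
  ab <- beta_from_mode(ctx$sd_y)
  lp <- stats::dnorm(slope, 0, ctx$slope_sd, log = TRUE) +
    stats::dnorm(intercept, mean(ctx$y), 1, log = TRUE) +
    stats::dbeta(sigma, ab["a"], ab["b"], log = TRUE)
  lp + ll
}

score_steps <- function(ctx, steptime, left, right, sigma) {
  S <- outer(ctx$t, steptime, "<")
  M <- sweep(S, 2, left, "*") + sweep(!S, 2, right, "*")
  R <- ctx$y - M
  ll <- -ctx$n * log(sigma * sqrt(2 * pi)) - colSums(R^2) / (2 * sigma^2)
  ab <- beta_from_mode(ctx$sd_y)
  lp <- -log(length(ctx$step_idx)) +
    stats::dnorm(left, mean(ctx$y), 1, log = TRUE) +
    stats::dnorm(right, mean(ctx$y), 1, log = TRUE) +
    stats::dbeta(sigma, ab["a"], ab["b"], log = TRUE)
  lp + ll
}

#' Classify one trial as ramp or step
#'
#' Runs `n_traces` independent inference traces. Each trace performs
#' `n_rounds` rounds of importance resampling: a fair coin picks the
#' hypothesis class for the round, a fresh data-driven proposal of that class
#' is drawn and scored, and the best-scoring hypothesis seen so far is
#' retained. `p_ramp` is the fraction of traces whose final best hypothesis is
#' a ramp. The signal is min-max normalised before inference; classification
#' is therefore invariant to affine rescaling.
#'
#' @param signal Trial ramping-interval signal (raw units allowed).
#' @param fs Sampling rate of the interval, Hz.
#' @param n_traces,n_rounds Importance-resampling budget.
#' @param seed Optional seed.
#' @return List of class `trial_classification`: `p_ramp`, `traces` tibble
#'   (`trace`, `class`, `score`), `best_step_time` (best step hypothesis over
#'   all traces, for alignment), `best_score_path` (per-trace non-decreasing
#'   best scores).
#' @export
classify_trial <- function(signal, fs = 100, n_traces = 20, n_rounds = 50,
                           seed = NULL) {
  seed_rng(seed)
  if (length(signal) < 10 || length(signal) / fs < 0.1) {
    abort("interval too short to classify")
  }
  y <- minmax_scale(signal)
  if (anyNA(y)) y <- rep(0.5, length(signal))
  ctx <- trial_context(y, fs)

  trace_class <- character(n_traces)
  trace_score <- numeric(n_traces)
  best_step_time <- NA_real_
  best_step_score <- -Inf
  score_paths <- vector("list", n_traces)
  for (tr in seq_len(n_traces)) {
    cls <- sample(c("ramp", "step"), n_rounds, replace = TRUE)
    nr <- sum(cls == "ramp")
    ns <- n_rounds - nr
    scores <- numeric(n_rounds)
    r_scores <- numeric(0)
    if (nr > 0) {
      k <- sample.int(nrow(ctx$pool), nr, replace = TRUE)
      ab <- beta_from_mode(ctx$sd_y)
      slope <- stats::rnorm(nr, ctx$pool[k, 1], ctx$slope_sd)
      inter <- stats::rnorm(nr, ctx$pool[k, 2], ctx$inter_sd)
      sig <- stats::rbeta(nr, ab["a"], ab["b"])
      r_scores <- score_ramps(ctx, slope, inter, sig)
    }
    s_scores <- numeric(0)
    s_times <- numeric(0)
    if (ns > 0) {
      i <- ctx$step_idx[sample.int(length(ctx$step_idx), ns, replace = TRUE)]
      lm_ <- vapply(i, function(ii) mean(ctx$y[seq_len(ii - 1L)]), numeric(1))
      rm_ <- vapply(i, function(ii) mean(ctx$y[ii:ctx$n]), numeric(1))
      ls_ <- vapply(i, function(ii) {
        v <- ctx$y[seq_len(ii - 1L)]
        if (length(v) > 1) max(stats::sd(v), 1e-3) else 1e-3
      }, numeric(1))
      rs_ <- vapply(i, function(ii) {
        v <- ctx$y[ii:ctx$n]
        if (length(v) > 1) max(stats::sd(v), 1e-3) else 1e-3
      }, numeric(1))
      ab <- beta_from_mode(ctx$sd_y)
      left <- stats::rnorm(ns, lm_, ls_)
      right <- stats::rnorm(ns, rm_, rs_)
      sigs <- stats::rbeta(ns, ab["a"], ab["b"])
      s_times <- ctx$t[i]
      s_scores <- score_steps(ctx, s_times, left, right, sigs)
    }
    scores[cls == "ramp"] <- r_scores
    scores[cls == "step"] <- s_scores
    best <- cummax(scores)
    score_paths[[tr]] <- best
    w <- which.max(scores)
    trace_class[tr] <- cls[w]
    trace_score[tr] <- scores[w]
    if (ns > 0) {
      ws <- which.max(s_scores)
      if (s_scores[ws] > best_step_score) {
        best_step_score <- s_scores[ws]
        best_step_time <- s_times[ws]
      }
    }
  }
  structure(
    list(
      p_ramp = mean(trace_class == "ramp"),
      traces = tibble(trace = seq_len(n_traces), class = trace_class,
                      score = trace_score),
      best_step_time = best_step_time,
      best_score_path = score_paths
    ),
    class = "trial_classification"
  )
}

#' Classify every valid trial of a session
#'
#' Applies [classify_trial()] to each valid ramping interval.
#'
#' @param intervals A [ramping_intervals()] tibble (built with
#'   `out_rate = 100` recommended).
#' @param n_traces,n_rounds Budget per trial.
#' @param seed Base seed; trial `i` uses `seed + i`.
#' @return Tibble: `trial`, `first_lick_time`, `p_ramp`, `best_step_time`
#'   (seconds from interval start), `best_class`.
#' @export
classify_session <- function(intervals, n_traces = 20, n_rounds = 50,
                             seed = 1) {
  fs <- attr(intervals, "fs")
  keep <- which(intervals$valid &
                  vapply(intervals$signal, length, integer(1)) >= 10)
  purrr::map_dfr(keep, function(i) {
    cl <- classify_trial(intervals$signal[[i]], fs = fs, n_traces = n_traces,
                         n_rounds = n_rounds, seed = seed + i)
    tibble(trial = intervals$trial[i],
           first_lick_time = intervals$first_lick_time[i],
           p_ramp = cl$p_ramp,
           best_step_time = cl$best_step_time,
           best_class = ifelse(cl$p_ramp >= 0.5, "ramp", "step"))
  })
}

#' Step-aligned average
#'
#' Aligns each trial's signal at its optimal step time and averages over
#' trials within a symmetric window. Under true step dynamics the average is a
#' clean step; under true ramps it is a transient superimposed on a
#' background ramp with positive slope, the diagnostic used to reject the
#' step account.
#'
#' @param intervals A [ramping_intervals()] tibble.
#' @param step_times Per-trial step times, seconds from interval start (as
#'   from [classify_session()]'s `best_step_time`).
#' @param window Half-window, seconds.
#' @return Tibble: `t` (s, step-aligned), `mean`, `n`.
#' @export
step_aligned_average <- function(intervals, step_times, window = 1) {
  fs <- attr(intervals, "fs")
  rel <- seq(round(-window * fs), round(window * fs))
  acc <- numeric(length(rel))
  cnt <- integer(length(rel))
  keep <- which(intervals$valid & !is.na(step_times))
  for (i in keep) {
    v <- intervals$signal[[i]]
    i0 <- round(step_times[i] * fs) + 1L
    idx <- i0 + rel
    ok <- idx >= 1L & idx <= length(v)
    acc[ok] <- acc[ok] + v[idx[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  tibble(t = rel / fs, mean = ifelse(cnt > 0, acc / cnt, NA_real_), n = cnt)
}

#' Cross-trial variance profile over the timed interval
#'
#' Pools trials by first-lick second (1-2 s, 2-3 s, ...), truncates each pool
#' at its earliest first lick, and measures cross-trial signal variance at 10%
#' increments of the truncated interval. Under uniformly timed steps the
#' variance is an inverted U peaking mid-interval; under common-endpoint
#' ramps it decreases toward the lick. Reports the curvature sign (quadratic
#' coefficient) and the Spearman correlation of variance with interval
#' position.
#'
#' @param intervals A [ramping_intervals()] tibble (signals enter in their
#'   original units; per-trial normalisation would erase the baseline-offset
#'   variance the profile is designed to expose).
#' @param min_pool Minimum trials per pool.
#' @param increments Number of interval landmarks (10 = 10% steps).
#' @return List: `profile` tibble (`pool`, `frac`, `variance`, `n`),
#'   `curvature` (quadratic coefficient of pooled variance vs fraction),
#'   `spearman_rho`.
#' @export
step_variance_profile <- function(intervals, min_pool = 20, increments = 10) {
  fs <- attr(intervals, "fs")
  d <- intervals[intervals$valid, ]
  d$pool <- floor(d$first_lick_time)
  fracs <- seq(0, 1, length.out = increments + 1)
  rows <- list()
  for (p in sort(unique(d$pool))) {
    dp <- d[d$pool == p, ]
    if (nrow(dp) < min_pool) next
    t_tr <- min(dp$first_lick_time) - 1.3   # truncated interval length, s
    n_tr <- max(2L, floor(t_tr * fs))
    M <- t(vapply(dp$signal, function(v) {
      v[pmin(length(v), round(fracs * (n_tr - 1)) + 1L)]
    }, numeric(length(fracs))))
    rows[[length(rows) + 1L]] <- tibble(
      pool = p, frac = fracs,
      variance = apply(M, 2, stats::var), n = nrow(dp))
  }
  if (!length(rows)) abort("no pool reaches the minimum trial count")
  prof <- dplyr::bind_rows(rows)
  agg <- prof |> dplyr::group_by(frac) |>
    dplyr::summarise(variance = mean(.data$variance), .groups = "drop")
  q <- stats::lm(variance ~ frac + I(frac^2), data = agg)
  rho <- if (stats::sd(agg$variance) == 0) {
    NA_real_
  } else {
    stats::cor(agg$frac, agg$variance, method = "spearman")
  }
  list(profile = prof, curvature = unname(stats::coef(q)[3]),
       spearman_rho = rho)
}
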