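#' Draw first-lick times with the scalar timing property
#'
#' Samples self-timed first-lick latencies from a log-normal distribution whose
#' moments are matched to `mean` and `weber_fraction * mean`, so the
#' coefficient of variation is invariant to the mean (Weber's law). Draws are
#' truncated below at 0.05 s.
#'
#' @param n Number of draws.
#' @param mean Mean latency, seconds.
#' @param weber_fraction Coefficient of variation (SD / mean).
#' @param seed Optional integer seed.
#' @return Numeric vector of latencies in seconds.
#' @export
#' @examples
#' t1 <- sample_first_lick_times(1000, mean = 3.3, weber_fraction = 0.3, seed = 1)
#' sd(t1) / mean(t1)
sample_first_lick_times <- function(n, mean, weber_fraction, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  if (mean <= 0) abort("`mean` must be positive.")
  if (weber_fraction <= 0) abort("`weber_fraction` must be positive.")
  seed_rng(seed)
  s <- weber_fraction * mean
  sdlog <- sqrt(log(1 + (s / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(stats::rlnorm(n, meanlog, sdlog), 0.05)
}

# redraw from the empirical distribution of `times` with its discrete hazard
# multiplied by m. Sampled atoms are smeared uniformly over the gap to the
# previous atom (linearly interpolated inverse cdf), so redraws are
# continuous and, at m = 1, equal in law to the base sample. Probability mass
# not exhausted by the multiplied hazard (m < 1) falls beyond the last atom
# and is returned as NA (no lick).
hazard_multiplied_sample <- function(times, m, n_out) {
  atoms <- sort(times)
  n <- length(atoms)
  h <- pmin(m / (n - seq_len(n) + 1), 1)
  surv <- cumprod(1 - h)
  pmf <- h * c(1, surv[-n])
  leftover <- surv[n]
  idx <- sample.int(n + 1L, n_out, replace = TRUE, prob = c(pmf, leftover))
  lo <- c(max(atoms[1] - (atoms[2] - atoms[1]), 0.05), atoms[-n])
  u <- stats::runif(n_out)
  ifelse(idx > n, NA_real_, lo[pmin(idx, n)] +
           u * (atoms[pmin(idx, n)] - lo[pmin(idx, n)]))
}

#' Build a trial table from first-lick latencies
#'
#' Assigns each latency a lamp-off time, a uniformly delayed cue time on the
#' session clock, and an outcome label given the task windows. When `opto` is
#' supplied, the given fraction of trials is flagged at random and their
#' first-lick latency is redrawn from the distribution whose hazard is the
#' empirical hazard of the input latencies multiplied by `hazard_multiplier`
#' (stimulation spans cue to first lick).
#'
#' @param times Numeric first-lick latencies (seconds post-cue; `NA` = no lick).
#' @param cfg A [task_config()].
#' @param opto `NULL` or `list(fraction =, hazard_multiplier =)`.
#' @param seed Optional integer seed.
#' @param session_start Seconds of padding before the first lamp-off event.
#' @return A tibble with one row per trial: `trial`, `lampoff_time`,
#'   `cue_time`, `first_lick_time` (post-cue), `outcome`, `opto_on`.
#' @export
build_trial_timeline <- function(times, cfg = task_config(), opto = NULL,
                                 seed = NULL, session_start = 30) {
  if (any(times < 0, na.rm = TRUE)) abort("first-lick times must be non-negative")
  seed_rng(seed)
  n <- length(times)
  opto_on <- rep(FALSE, n)
  if (!is.null(opto)) {
    opto_on <- seq_len(n) %in% sample.int(n, round(opto$fraction * n))
    if (any(opto_on)) {
      base <- times[!is.na(times)]
      times[opto_on] <- hazard_multiplied_sample(base, opto$hazard_multiplier,
                                                 sum(opto_on))
    }
  }
  delays <- stats::runif(n, cfg$lampoff_delay_range[1], cfg$lampoff_delay_range[2])
  # each trial occupies lamp-off -> cue -> cue + iti_end; next lamp-off follows
  cue <- numeric(n)
  lampoff <- numeric(n)
  t0 <- session_start
  for (i in seq_len(n)) {
    lampoff[i] <- t0
    cue[i] <- t0 + delays[i]
    t0 <- cue[i] + cfg$iti_end
  }
  tibble(
    trial = seq_len(n),
    lampoff_time = lampoff,
    cue_time = cue,
    first_lick_time = times,
    outcome = classify_outcome(times, cfg),
    opto_on = opto_on
  )
}

# first-order rise/decay transient, unit peak scaled to `amplitude`
transient_kernel <- function(k, fs, support = 1.5) {
  t <- seq(0, support, by = 1 / fs)
  y <- (1 - exp(-t / k$rise)) * exp(-t / k$decay)
  if (max(y) > 0) y <- y / max(y)
  k$amplitude * y
}

add_at_events <- function(x, kernel, event_times, fs, pre = 0) {
  n <- length(x)
  kl <- length(kernel)
  for (et in event_times) {
    i0 <- time_index(et - pre, fs)
    if (is.na(i0)) next
    idx <- i0:min(n, i0 + kl - 1L)
    idx <- idx[idx >= 1L]
    if (!length(idx)) next
    x[idx] <- x[idx] + kernel[seq_along(idx) + (idx[1] - i0)]
  }
  x
}

#' Synthesise the continuous channels of a session
#'
#' Renders a trial table into continuous fluorescence and movement channels
#' with known per-trial ground truth. The signal channel receives a
#' movement-time-dependent baseline offset, a latent ramp (or step) ending at a
#' common amplitude, cue/lick/reward transients, shared movement artifacts,
#' white noise, and multiplicative exponential bleaching. The control channel
#' shares bleaching, artifacts and noise but has no timing structure. EMG and
#' accelerometer channels carry bursts at licks and artifact events.
#'
#' @param trials Trial table from [build_trial_timeline()].
#' @param gp A [generative_params()].
#' @param cfg A [task_config()].
#' @param seed Optional integer seed.
#' @return A `ramp_session` object: list with `channels` (tibble: `time`,
#'   `gcamp`, `control`, `emg`, `accel`), `events` (named list of times),
#'   `trials` (with ground-truth columns), `config`, `params`, `seed`.
#' @export
synthesize_session <- function(trials, gp = generative_params(),
                               cfg = task_config(), seed = NULL) {
  seed_rng(seed)
  fs <- cfg$sampling_rate
  if (any(diff(trials$lampoff_time) <= 0)) abort("overlapping trials in table")
  t_end <- max(trials$cue_time) + cfg$iti_end + 5
  nsamp <- time_index(t_end, fs)
  tgrid <- (seq_len(nsamp) - 1) / fs

  licked <- !is.na(trials$first_lick_time)
  lick_abs <- trials$cue_time[licked] + trials$first_lick_time[licked]
  reward_abs <- with(trials[licked & trials$outcome == "reward", ],
                     cue_time + first_lick_time)

  latent <- numeric(nsamp)
  baseline <- numeric(nsamp)
  gt_offset <- rep(NA_real_, nrow(trials))
  gt_slope <- rep(NA_real_, nrow(trials))
  gt_step <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    T_i <- trials$first_lick_time[i]
    if (is.na(T_i)) next
    cue_i <- trials$cue_time[i]
    lick_i <- cue_i + T_i
    # baseline offset active from 3 s before lamp-off through the first lick
    jit <- if ((gp$baseline_noise %||% 0) > 0) {
      exp(stats::rnorm(1, 0, gp$baseline_noise))
    } else {
      1
    }
    off <- gp$baseline_gain / T_i * jit
    gt_offset[i] <- off
    ib <- time_index(max(0, trials$lampoff_time[i] - 3), fs):time_index(lick_i, fs)
    baseline[ib] <- baseline[ib] + off
    if (gp$dynamics_mode == "ramp") {
      onset <- cue_i + gp$ramp_onset_lag
      if (lick_i > onset) {
        slope <- gp$ramp_peak_amplitude / (T_i - gp$ramp_onset_lag)
        gt_slope[i] <- slope
        ir <- time_index(onset, fs):time_index(lick_i, fs)
        latent[ir] <- latent[ir] + slope * (tgrid[ir] - onset)
      }
    } else {
      st <- stats::runif(1, 0, T_i)
      gt_step[i] <- st
      is_ <- time_index(cue_i + st, fs):time_index(lick_i, fs)
      latent[is_] <- latent[is_] + gp$ramp_peak_amplitude
    }
  }

  sig <- gp$f_rest + baseline + latent
  sig <- add_at_events(sig, transient_kernel(gp$cue_kernel, fs), trials$cue_time, fs)
  sig <- add_at_events(sig, transient_kernel(gp$lick_kernel, fs), lick_abs, fs)
  sig <- add_at_events(sig, transient_kernel(gp$reward_kernel, fs), reward_abs, fs)

  n_art <- stats::rpois(1, gp$artifact_rate * t_end)
  art_times <- sort(stats::runif(n_art, 0, t_end - 1))
  art_kernel <- transient_kernel(
    list(amplitude = gp$artifact_amplitude, rise = 0.005, decay = 0.03), fs, 0.25)
  artifact <- add_at_events(numeric(nsamp), art_kernel, art_times, fs)

  noise <- function() stats::rnorm(nsamp, 0, gp$noise_sd)
  bleach_sig <- exp(-tgrid / gp$bleach_tau)
  bleach_ctl <- exp(-tgrid / (0.8 * gp$bleach_tau))
  gcamp <- bleach_sig * (sig + artifact + noise())
  control <- bleach_ctl * (0.7 * gp$f_rest + artifact + noise())

  burst <- transient_kernel(list(amplitude = 1, rise = 0.002, decay = 0.02), fs, 0.15)
  emg <- add_at_events(numeric(nsamp), burst, c(lick_abs, art_times), fs)
  accel <- add_at_events(numeric(nsamp), burst, art_times, fs)
  emg <- emg + stats::rnorm(nsamp, 0, 0.02)
  accel <- accel + stats::rnorm(nsamp, 0, 0.02)

  trials$gt_baseline_offset <- gt_offset
  trials$gt_ramp_slope <- gt_slope
  trials$gt_step_time <- gt_step

  opto_pulses <- numeric(0)
  if (any(trials$opto_on)) {
    stim <- trials[trials$opto_on & licked_vec(trials), ]
    opto_pulses <- unlist(lapply(seq_len(nrow(stim)), function(i) {
      seq(stim$cue_time[i], stim$cue_time[i] + stim$first_lick_time[i], by = 0.1)
    }))
  }

  structure(
    list(
      channels = tibble(time = tgrid, gcamp = gcamp, control = control,
                        emg = emg, accel = accel),
      events = list(
        lampoff = trials$lampoff_time,
        cue = trials$cue_time,
        licks = lick_abs,
        reward = reward_abs,
        opto = opto_pulses,
        artifact = art_times
      ),
      trials = trials,
      config = cfg,
      params = gp,
      seed = seed
    ),
    class = "ramp_session"
  )
}

licked_vec <- function(trials) !is.na(trials$first_lick_time)

#' Simulate a complete synthetic session
#'
#' Convenience wrapper chaining [sample_first_lick_times()],
#' [build_trial_timeline()] and [synthesize_session()] under a single seed.
#'
#' @inheritParams synthesize_session
#' @param seed Integer seed controlling every random draw.
#' @return A `ramp_session`.
#' @export
#' @examples
#' s <- simulate_session(generative_params(n_trials = 20),
#'                       task_config(sampling_rate = 200), seed = 1)
#' s$trials
simulate_session <- function(gp = generative_params(), cfg = task_config(),
                             seed = 1) {
  seed_rng(seed)
  times <- sample_first_lick_times(gp$n_trials, gp$mean_move_time,
                                   gp$weber_fraction)
  trials <- build_trial_timeline(times, cfg, opto = gp$opto)
  s <- synthesize_session(trials, gp, cfg)
  s$seed <- seed
  s
}

#' Simulate a session with an exactly logistic movement hazard
#'
#' Generates a session in which the per-timepoint (10 ms) probability of
#' transitioning to movement is exactly `inverse-logit(beta0 + beta1 * s(t))`,
#' where `s(t)` is a per-trial latent ramp (slope drawn per trial) plus white
#' noise. This is the positive control for the movement-state decoder: the
#' decoding model is well-specified for these data, so the fitted hazard
#' should recover the empirical hazard up to sampling noise. The signal is
#' written into the `gcamp` channel at 100 Hz; other channels are omitted.
#'
#' @param n_trials Number of trials.
#' @param beta0,beta1 Logistic intercept and slope (per 10-ms sample).
#' @param slope_range Range of per-trial latent ramp durations: the latent
#'   rises at `1 / runif(slope_range)` per second, capped at `cap`.
#' @param cap Latent ceiling.
#' @param noise_sd Additive white-noise SD on the signal.
#' @param seed Seed.
#' @return A `ramp_session` with channels `time`, `gcamp`.
#' @export
simulate_logistic_session <- function(n_trials = 500, beta0 = -7.5,
                                      beta1 = 3, slope_range = c(2.5, 6),
                                      cap = 1.2, noise_sd = 0.1, seed = 1) {
  seed_rng(seed)
  fs <- 100
  cfg <- task_config(sampling_rate = fs)
  cue <- numeric(n_trials)
  lampoff <- numeric(n_trials)
  lick <- numeric(n_trials)
  t0 <- 30
  sigs <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    lampoff[i] <- t0
    cue[i] <- t0 + stats::runif(1, cfg$lampoff_delay_range[1],
                                cfg$lampoff_delay_range[2])
    slope <- 1 / stats::runif(1, slope_range[1], slope_range[2])
    tt <- seq(0, cfg$iti_end - 0.01, by = 1 / fs)
    sv <- pmin(slope * tt, cap) + stats::rnorm(length(tt), 0, noise_sd)
    p <- inv_logit(beta0 + beta1 * sv)
    moved <- which(stats::runif(length(tt)) < p & tt > 0.2)
    lick[i] <- if (length(moved)) tt[moved[1]] else NA_real_
    sigs[[i]] <- sv
    t0 <- cue[i] + cfg$iti_end
  }
  nsamp <- round((max(cue) + cfg$iti_end + 1) * fs) + 1L
  g <- numeric(nsamp)
  for (i in seq_len(n_trials)) {
    i0 <- round(cue[i] * fs) + 1L
    g[i0:(i0 + length(sigs[[i]]) - 1L)] <- sigs[[i]]
  }
  trials <- tibble(
    trial = seq_len(n_trials), lampoff_time = lampoff, cue_time = cue,
    first_lick_time = lick, outcome = classify_outcome(lick, cfg),
    opto_on = FALSE
  )
  structure(
    list(channels = tibble(time = (seq_len(nsamp) - 1) / fs, gcamp = g),
         events = list(lampoff = lampoff, cue = cue,
                       licks = cue[!is.na(lick)] + lick[!is.na(lick)]),
         trials = trials, config = cfg,
         params = list(beta0 = beta0, beta1 = beta1, noise_sd = noise_sd),
         seed = seed),
    class = "ramp_session"
  )
}

#' @export
print.ramp_session <- function(x, ...) {
  cat(sprintf(
    "<ramp_session> %d trials, %.0f s at %g Hz, mode = %s\n",
    nrow(x$trials), max(x$channels$time), x$config$sampling_rate,
    x$params$dynamics_mode))
  print(utils::head(x$trials, 3))
  invisible(x)
}
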