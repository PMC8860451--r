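#' Extract per-trial ramping intervals
#'
#' Cuts each trial's signal from 0.7 s after the cue to 0.6 s before the first
#' lick (buffers excluding the sensory and motor transients), smooths with a
#' 100-ms Gaussian kernel, and flags validity: the interval must last at least
#' 0.1 s and the first lick must fall between 1.4 s and the end of the trial
#' window.
#'
#' @param session A `ramp_session`.
#' @param dff Signal trace at the session sampling rate.
#' @param smooth_sigma Gaussian smoothing SD, seconds (0 disables).
#' @param out_rate Optional sampling rate to decimate intervals to, Hz.
#' @return Tibble: `trial`, `first_lick_time`, `t0`, `t1` (session clock),
#'   `valid`, `signal` (list-column).
#' @export
ramping_intervals <- function(session, dff, smooth_sigma = 0.1,
                              out_rate = NULL) {
  fs <- session$config$sampling_rate
  x <- as.numeric(dff)
  if (smooth_sigma > 0) x <- gaussian_smooth(x, smooth_sigma, fs)
  step <- if (is.null(out_rate)) 1L else max(1L, round(fs / out_rate))
  tr <- session$trials
  lick_ok <- !is.na(tr$first_lick_time) &
    tr$first_lick_time >= 1.4 & tr$first_lick_time <= session$config$iti_end
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    if (!lick_ok[i]) {
      return(tibble(trial = i, first_lick_time = tr$first_lick_time[i],
                    t0 = NA_real_, t1 = NA_real_, valid = FALSE,
                    signal = list(numeric(0))))
    }
    t0 <- tr$cue_time[i] + 0.7
    t1 <- tr$cue_time[i] + tr$first_lick_time[i] - 0.6
    valid <- (t1 - t0) >= 0.1
    sig <- if (valid) x[seq(time_index(t0, fs), time_index(t1, fs), by = step)]
           else numeric(0)
    tibble(trial = i, first_lick_time = tr$first_lick_time[i],
           t0 = t0, t1 = t1, valid = valid, signal = list(sig))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- fs / step
  new_ramptime_result(out, "ramping_intervals")
}

# crossing index of one signal: first low-to-high passage after which the
# signal stays at or above `level` to the end; 0 encodes no valid crossing
crossing_index <- function(v, level) {
  n <- length(v)
  if (n == 0L) return(0L)
  below <- which(v < level)
  if (!length(below)) {
    # starting exactly at the level and staying above counts as a crossing
    # at the first sample; starting strictly above does not
    return(if (v[1] <= level) 1L else 0L)
  }
  k <- below[length(below)]
  if (k == n) return(0L)                # ends below: never stays above
  k + 1L
}

#' Debounced threshold-crossing times
#'
#' For each valid ramping interval, finds the first time the signal crosses
#' `level` from low to high and remains above it through the end of the
#' interval. Crossing times are normalised by interval length to (0, 1];
#' trials that never cross (including those starting and ending above the
#' level) are encoded as 0.
#'
#' @param intervals A [ramping_intervals()] tibble.
#' @param level Threshold level in signal units.
#' @return Tibble: `trial`, `crossed`, `norm_time` (0 if no crossing),
#'   `abs_time` (seconds post-cue, `NA` if no crossing).
#' @export
debounced_crossing_times <- function(intervals, level) {
  fs <- attr(intervals, "fs")
  purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    if (!intervals$valid[i]) {
      return(tibble(trial = intervals$trial[i], crossed = FALSE,
                    norm_time = 0, abs_time = NA_real_))
    }
    v <- intervals$signal[[i]]
    k <- crossing_index(v, level)
    if (k == 0L) {
      tibble(trial = intervals$trial[i], crossed = FALSE, norm_time = 0,
             abs_time = NA_real_)
    } else {
      tibble(trial = intervals$trial[i], crossed = TRUE,
             norm_time = k / length(v),
             abs_time = (intervals$t0[i] + (k - 1) / fs) -
               (intervals$t0[i] - 0.7))
    }
  })
}

#' Select unbiased threshold levels
#'
#' Scans 100 evenly spaced candidate levels spanning the minimum-to-maximum of
#' the pooled ramping-interval signals and selects: `mid`, the lowest level
#' with the maximum number of crossing trials; `min` and `max`, the lowest and
#' highest levels with at least 50 crossing trials. In relaxed mode (used for
#' the control channel, whose noisy signals rarely satisfy the debouncing
#' constraint) the 50-trial floor is dropped and the most-crossed level is
#' taken, flagged as relaxed.
#'
#' @param intervals A [ramping_intervals()] tibble.
#' @param n_levels Number of candidate levels.
#' @param relaxed Drop the 50-crossing floor.
#' @param min_crossings Crossing floor for the min/max levels.
#' @return List of class `threshold_set`: `levels`, `crossings`, `mid`,
#'   `min`, `max` (each a list with `level` and `n_crossing`; `NA` when no
#'   level qualifies), `relaxed`, `any_crossing`.
#' @export
select_thresholds <- function(intervals, n_levels = 100, relaxed = FALSE,
                              min_crossings = 50) {
  sigs <- intervals$signal[intervals$valid]
  if (!length(sigs)) abort("no valid ramping intervals")
  pooled <- unlist(sigs)
  levels <- seq(min(pooled), max(pooled), length.out = n_levels)
  ncross <- vapply(levels, function(lv) {
    sum(vapply(sigs, function(v) crossing_index(v, lv) > 0L, logical(1)))
  }, numeric(1))
  pick <- function(idx) {
    if (!length(idx)) list(level = NA_real_, n_crossing = 0L)
    else list(level = levels[idx], n_crossing = as.integer(ncross[idx]))
  }
  mid <- pick(which(ncross == max(ncross))[1])
  if (relaxed) {
    lo <- hi <- mid
  } else {
    ok <- which(ncross >= min_crossings)
    lo <- pick(utils::head(ok, 1))
    hi <- pick(utils::tail(ok, 1))
  }
  structure(
    list(levels = levels, crossings = ncross, mid = mid, min = lo, max = hi,
         relaxed = relaxed, any_crossing = max(ncross) > 0),
    class = "threshold_set"
  )
}

decoder_groups <- c("x0", "prev_lick", "out_reaction", "out_early",
                    "out_reward", "out_iti", "iti_median", "loi_median",
                    "control_cross", "signal_cross")

#' Nested decoder of log first-lick time
#'
#' Predicts `log(first-lick time)` per trial from nested predictor groups
#' added in order: previous-trial first-lick time; previous-trial outcome
#' indicators (reaction, early, reward, ITI lick; no-lick is the implicit
#' all-zero level); the median signal in the 10-s window before lamp-off
#' ("ITI"); the median signal between lamp-off and cue ("LOI"); the
#' control-channel debounced threshold-crossing time (relaxed threshold); and
#' the signal-channel crossing time at the mid threshold. Predictors are
#' min-max normalised to (0, 1); a predictor with no crossing anywhere is a
#' constant-ones column. Ridge with five-fold CV blocked by trial, as in the
#' encoding model; held-out R-squared is reported per nest.
#'
#' @param session A `ramp_session`.
#' @param dff,control_dff Signal and control dF/F traces.
#' @param folds CV folds.
#' @param lambdas Ridge grid.
#' @param seed Fold-assignment seed.
#' @return A `nested_fit` with a `decoder_data` attribute (per-trial predictor
#'   tibble).
#' @export
fit_timelick_decoder <- function(session, dff, control_dff = NULL, folds = 5,
                                 lambdas = 10^seq(-3, 3, length.out = 13),
                                 seed = 1) {
  fs <- session$config$sampling_rate
  tr <- session$trials
  iv_sig <- ramping_intervals(session, dff, out_rate = 100)
  cross_sig <- debounced_crossing_times(
    iv_sig, select_thresholds(iv_sig)$mid$level)
  if (is.null(control_dff)) {
    cross_ctl <- tibble(trial = cross_sig$trial, norm_time = 0,
                        crossed = FALSE)
    ctl_any <- FALSE
  } else {
    iv_ctl <- ramping_intervals(session, control_dff, out_rate = 100)
    ts_ctl <- select_thresholds(iv_ctl, relaxed = TRUE)
    cross_ctl <- debounced_crossing_times(iv_ctl, ts_ctl$mid$level)
    ctl_any <- ts_ctl$any_crossing
  }

  keep <- which(iv_sig$valid)
  if (length(keep) < 20) abort("fewer than 20 usable trials")
  x <- as.numeric(dff)
  med_win <- function(i, w0, w1) {
    idx <- max(1L, time_index(w0, fs)):time_index(w1, fs)
    stats::median(x[idx])
  }
  prev <- function(v) c(NA, v[-length(v)])
  prev_lick <- prev(tr$first_lick_time)
  prev_out <- prev(as.character(tr$outcome))
  dat <- tibble(
    trial = keep,
    y = log(tr$first_lick_time[keep]),
    prev_lick = ifelse(is.na(prev_lick[keep]), 0, prev_lick[keep]),
    out_reaction = as.numeric(prev_out[keep] %in% "reaction"),
    out_early = as.numeric(prev_out[keep] %in% "early"),
    out_reward = as.numeric(prev_out[keep] %in% "reward"),
    out_iti = as.numeric(prev_out[keep] %in% "iti_lick"),
    iti_median = vapply(keep, function(i)
      med_win(i, tr$lampoff_time[i] - 10, tr$lampoff_time[i]), numeric(1)),
    loi_median = vapply(keep, function(i)
      med_win(i, tr$lampoff_time[i], tr$cue_time[i]), numeric(1)),
    control_cross = if (ctl_any) cross_ctl$norm_time[match(keep, cross_ctl$trial)]
                    else rep(1, length(keep)),
    signal_cross = if (any(cross_sig$crossed))
                     cross_sig$norm_time[match(keep, cross_sig$trial)]
                   else rep(1, length(keep))
  )
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) v else (v - r[1]) / diff(r)
  }
  pred_cols <- setdiff(decoder_groups, "x0")
  Xd <- cbind(x0 = 1, as.matrix(dplyr::mutate(dat[pred_cols],
                                              dplyr::across(dplyr::everything(), norm01))))
  fit <- nested_ridge(dat$y, Xd, groups = c("x0", pred_cols), decoder_groups,
                      fold_id = dat$trial, folds = folds, lambdas = lambdas,
                      seed = seed)
  # held-out R^2 per nest from the CV test loss against the null variance
  var_y <- mean((dat$y - mean(dat$y))^2)
  fit$nests$r_squared_cv <- 1 - fit$nests$test_loss / var_y
  attr(fit, "decoder_data") <- dat
  fit
}

#' Threshold-level slope analysis of crossing times
#'
#' Regresses the absolute crossing time (seconds post-cue) on the first-lick
#' time at each of the low/mid/high thresholds, among trials that cross. A
#' slope rising with threshold level is the signature of single-trial ramps to
#' a common endpoint; a level-independent slope is the signature of a
#' single-step dynamic.
#'
#' @param intervals A [ramping_intervals()] tibble.
#' @param thresholds A [select_thresholds()] result (or named list of levels).
#' @param min_trials Minimum crossing trials per level.
#' @return Tibble: `level_name`, `level`, `n`, `slope`, `ci_lo`, `ci_hi`,
#'   `r_squared`.
#' @export
threshold_slope_analysis <- function(intervals, thresholds, min_trials = 10) {
  lv <- list(low = thresholds$min, mid = thresholds$mid, high = thresholds$max)
  purrr::imap_dfr(lv, function(th, nm) {
    if (is.na(th$level)) {
      return(tibble(level_name = nm, level = NA_real_, n = 0L,
                    slope = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    r_squared = NA_real_))
    }
    cr <- debounced_crossing_times(intervals, th$level)
    d <- dplyr::inner_join(
      cr[cr$crossed, c("trial", "abs_time")],
      intervals[, c("trial", "first_lick_time")], by = "trial")
    if (nrow(d) < min_trials) {
      return(tibble(level_name = nm, level = th$level, n = nrow(d),
                    slope = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    r_squared = NA_real_))
    }
    m <- stats::lm(abs_time ~ first_lick_time, data = d)
    ci <- stats::confint(m)["first_lick_time", ]
    tibble(level_name = nm, level = th$level, n = nrow(d),
           slope = unname(stats::coef(m)["first_lick_time"]),
           ci_lo = ci[1], ci_hi = ci[2],
           r_squared = summary(m)$r.squared)
  })
}
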