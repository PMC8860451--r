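#' Remove photometric singularities by interpolation
#'
#' Replaces isolated samples lying more than `k` standard deviations from the
#' trace mean with linear interpolation between their neighbours. Only runs of
#' at most `max_run` consecutive flagged samples are treated as isolated;
#' longer excursions are left untouched and reported via the `runs_skipped`
#' attribute.
#'
#' @param trace Numeric raw fluorescence trace.
#' @param k Standard-deviation multiple defining a singularity.
#' @param max_run Longest run of consecutive flagged samples still treated as
#'   an isolated singularity.
#' @return The cleaned trace, with attributes `n_replaced` and `runs_skipped`.
#' @export
remove_singularities <- function(trace, k = 15, max_run = 3) {
  if (length(trace) < 3) abort("trace too short")
  mu <- mean(trace)
  sdv <- stats::sd(trace)
  bad <- abs(trace - mu) > k * sdv
  if (all(bad)) abort("all samples flagged; degenerate trace")
  if (!any(bad)) {
    return(structure(trace, n_replaced = 0L, runs_skipped = 0L))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  skipped <- 0L
  replaced <- 0L
  out <- trace
  for (j in which(r$values)) {
    len <- r$lengths[j]
    if (len > max_run) {
      skipped <- skipped + 1L
      next
    }
    i0 <- starts[j]; i1 <- ends[j]
    lo <- i0 - 1L; hi <- i1 + 1L
    if (lo < 1L) {
      out[i0:i1] <- out[hi]
    } else if (hi > length(out)) {
      out[i0:i1] <- out[lo]
    } else {
      out[i0:i1] <- out[lo] + (out[hi] - out[lo]) *
        seq_len(len) / (len + 1)
    }
    replaced <- replaced + len
  }
  structure(out, n_replaced = replaced, runs_skipped = skipped)
}

# FFT zero-phase low-pass: unit response up to fc, raised-cosine roll-off to
# zero at fc * 10^(2 * (1 - steepness)); used as the whole-session F0 estimator
lowpass_f0 <- function(x, fs, fc, steepness = 0.95) {
  n <- length(x)
  mu <- mean(x)
  X <- stats::fft(x - mu)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)   # two-sided frequency axis
  f_stop <- fc * 10^(2 * (1 - steepness))
  fsafe <- pmax(f, fc)
  H <- ifelse(f <= fc, 1,
              ifelse(f >= f_stop, 0,
                     0.5 * (1 + cos(pi * (log10(fsafe) - log10(fc)) /
                                      (log10(f_stop) - log10(fc))))))
  Re(stats::fft(X * H, inverse = TRUE)) / n + mu
}

trial_pre_windows <- function(trials, fs, n_total, pre = 5) {
  lapply(seq_len(nrow(trials)), function(i) {
    i1 <- time_index(trials$lampoff_time[i], fs) - 1L
    i0 <- i1 - round(pre * fs) + 1L
    if (i0 < 1L) NULL else i0:min(i1, n_total)
  })
}

# span of trial i on the session grid: lamp-off to next lamp-off (or end)
trial_spans <- function(trials, fs, n_total) {
  starts <- vapply(trials$lampoff_time, time_index, integer(1), fs = fs)
  ends <- c(starts[-1] - 1L, n_total)
  Map(function(a, b) a:min(b, n_total), starts, ends)
}

#' Bleach-corrected dF/F
#'
#' Computes `(F - F0) / F0` with the baseline `F0` estimated by one of four
#' methods: `"normalized_baseline"` (per trial, the mean fluorescence of the
#' 5 s preceding the trial), `"lowpass"` (a zero-phase low-pass of the whole
#' session, cutoff `fc`), `"multiple_baseline"` (per trial, the mean of the
#' 5-s pre-trial windows of trials n-5 ... n+5), and `"moving_average"` (a
#' centred 200-s moving average, window shrunk symmetrically at the session
#' edges). Trial-based methods flag and exclude trials lacking 5 s of
#' pre-trial data; their spans keep `NA`.
#'
#' @param trace Raw fluorescence (after [remove_singularities()]).
#' @param method One of the four baseline methods.
#' @param trials Trial table (required for trial-based methods).
#' @param fs Sampling rate, Hz.
#' @param window Moving-average window, seconds.
#' @param fc Low-pass cutoff, Hz.
#' @param steepness Low-pass steepness convention in (0.5, 1).
#' @return Numeric dF/F trace of the input length, class `dff_trace`, with
#'   attributes `method` and `params`.
#' @export
#' @examples
#' f <- 100 + rnorm(2000)
#' d <- compute_dff(f, "moving_average", fs = 100, window = 5)
compute_dff <- function(trace,
                        method = c("moving_average", "normalized_baseline",
                                   "lowpass", "multiple_baseline"),
                        trials = NULL, fs,
                        window = 200, fc = 5e-5, steepness = 0.95) {
  method <- match.arg(method)
  n <- length(trace)
  f0 <- switch(
    method,
    moving_average = moving_average_centered(trace, round(window / 2 * fs)),
    lowpass = lowpass_f0(trace, fs, fc, steepness),
    normalized_baseline = ,
    multiple_baseline = {
      if (is.null(trials)) abort("trial-based methods need `trials`")
      wins <- trial_pre_windows(trials, fs, n)
      means <- vapply(wins, function(w) if (is.null(w)) NA_real_ else mean(trace[w]),
                      numeric(1))
      ntr <- length(means)
      f0_trial <- if (method == "normalized_baseline") {
        means
      } else {
        vapply(seq_len(ntr), function(i) {
          idx <- max(1L, i - 5L):min(ntr, i + 5L)
          mean(means[idx], na.rm = TRUE)
        }, numeric(1))
      }
      f0v <- rep(NA_real_, n)
      spans <- trial_spans(trials, fs, n)
      for (i in seq_len(ntr)) f0v[spans[[i]]] <- f0_trial[i]
      # pre-session samples use the first trial's baseline
      first <- time_index(trials$lampoff_time[1], fs)
      f0v[seq_len(first - 1L)] <- f0_trial[1]
      f0v
    }
  )
  out <- (trace - f0) / f0
  excluded <- if (method %in% c("normalized_baseline", "multiple_baseline")) {
    which(vapply(trial_pre_windows(trials, fs, n), is.null, logical(1)))
  } else {
    integer(0)
  }
  structure(out, class = "dff_trace", method = method,
            params = list(fs = fs, window = window, fc = fc,
                          steepness = steepness),
            excluded_trials = excluded)
}

#' Paired-trial set for distortion analysis
#'
#' Finds consecutive trial pairs in which an early unrewarded trial
#' (first-lick 0.7-2.9 s) is followed by a rewarded trial (3.4-7 s), the "ER"
#' ordering, or the reverse ("RE"). Each pair is associated with the window
#' from 20 s before to 20 s after the second trial's cue. Pairs whose window
#' crosses a session edge are dropped.
#'
#' @param trials Trial table.
#' @param session_span Two-element session time span, seconds.
#' @return Tibble: `kind` ("ER"/"RE"), `trial_a`, `trial_b`, `cue_b`.
#' @export
paired_trials <- function(trials, session_span) {
  t <- trials$first_lick_time
  is_e <- !is.na(t) & t >= 0.7 & t <= 2.9
  is_r <- !is.na(t) & t >= 3.4 & t <= 7
  n <- nrow(trials)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    kind <- if (is_e[i] && is_r[i + 1L]) "ER"
            else if (is_r[i] && is_e[i + 1L]) "RE"
            else next
    cue_b <- trials$cue_time[i + 1L]
    if (cue_b - 20 < session_span[1] || cue_b + 20 > session_span[2]) next
    rows[[length(rows) + 1L]] <-
      tibble(kind = kind, trial_a = i, trial_b = i + 1L, cue_b = cue_b)
  }
  dplyr::bind_rows(rows)
}

#' Distortion index of a dF/F method
#'
#' Quantifies artifactual amplitude scaling or baseline shifts introduced by a
#' dF/F method. For each paired-trial window (-20 to +20 s around the second
#' trial's cue), the raw fluorescence and the dF/F trace are min-max
#' normalised and the pointwise absolute difference `|F_hat - dFF_hat|` is
#' averaged over pairs. Zero whenever the dF/F is an affine rescaling of the
#' raw trace over the window. Flat windows are skipped with a warning. A 200-ms
#' moving-average smoothed profile is included for display.
#'
#' @param trace Raw fluorescence.
#' @param dff A `dff_trace` for the same session.
#' @param pairs Pairs from [paired_trials()].
#' @param fs Sampling rate, Hz.
#' @return Tibble of class `distortion_profile`: `t` (s, pair-cue-aligned),
#'   `di` (per-pair distortion, averaged over pairs), `di_avg` (distortion of
#'   the pair-averaged normalised traces — per-pair noise cancels, so the
#'   systematic component stands out), `di_smooth` (200-ms smoothed `di`);
#'   attribute `n_pairs`.
#' @export
distortion_index <- function(trace, dff, pairs, fs) {
  if (nrow(pairs) < 1) abort("need at least one trial pair")
  rel <- seq(round(-20 * fs), round(20 * fs))
  acc <- numeric(length(rel))
  f_acc <- numeric(length(rel))
  d_acc <- numeric(length(rel))
  used <- 0L
  for (i in seq_len(nrow(pairs))) {
    idx <- time_index(pairs$cue_b[i], fs) + rel
    f <- minmax_scale(trace[idx])
    d <- minmax_scale(as.numeric(dff)[idx])
    if (anyNA(f) || anyNA(d)) {
      warn("flat or incomplete pair window skipped")
      next
    }
    acc <- acc + abs(f - d)
    f_acc <- f_acc + f
    d_acc <- d_acc + d
    used <- used + 1L
  }
  if (used == 0L) abort("no usable pairs")
  di <- acc / used
  out <- tibble(t = rel / fs, di = di,
                di_avg = abs(f_acc - d_acc) / used,
                di_smooth = moving_average_centered(di, round(0.1 * fs)))
  new_ramptime_result(out, "distortion_profile", n_pairs = used)
}

#' Half-decay time of the lick-aligned transient
#'
#' Event-aligns the trace to qualifying events (by default unrewarded
#' first-licks 0.5-3.3 s after the cue), averages, and measures the time from
#' the transient peak to the first sample falling below half the
#' baseline-to-peak amplitude. Baseline is the mean of the 100 ms preceding
#' the event. Returns `NA` when the average never decays below the half
#' amplitude within the window.
#'
#' @param signal Numeric trace.
#' @param events Event times, seconds.
#' @param fs Sampling rate, Hz.
#' @param window Post-event search window, seconds.
#' @param min_events Minimum number of qualifying events.
#' @return Half-decay time in seconds, or `NA`.
#' @export
transient_half_decay <- function(signal, events, fs, window = 1,
                                 min_events = 10) {
  if (length(events) < min_events) {
    abort(sprintf("need >= %d events, got %d", min_events, length(events)))
  }
  rel <- seq(round(-0.1 * fs), round(window * fs))
  mats <- vapply(events, function(e) signal[time_index(e, fs) + rel],
                 numeric(length(rel)))
  avg <- rowMeans(mats)
  t <- rel / fs
  base <- mean(avg[t < -0.005])
  post <- which(t >= 0)
  pk <- post[which.max(avg[post])]
  half <- base + (avg[pk] - base) / 2
  below <- which(t > t[pk] & avg < half)
  if (!length(below)) return(NA_real_)
  t[below[1]] - t[pk]
}

#' Normalised dF/F in percent of the lick transient
#'
#' Rescales a dF/F trace to percent of the mean baseline-to-peak amplitude of
#' the lick-related transient, measured on trials with first-licks between 2
#' and 3 s. Baseline is the mean over 0.6-0.4 s before the lick; peak is the
#' maximum within 0.2 s of the lick. Invariant to multiplicative gain
#' differences between sensors.
#'
#' @param dff A `dff_trace`.
#' @param trials Trial table.
#' @param fs Sampling rate, Hz.
#' @return Rescaled trace (percent units), class `dff_trace`, attribute
#'   `lick_amplitude` in original units.
#' @export
normalized_dff <- function(dff, trials, fs) {
  x <- as.numeric(dff)
  sel <- !is.na(trials$first_lick_time) &
    trials$first_lick_time >= 2 & trials$first_lick_time <= 3
  if (sum(sel) < 5) abort("need >= 5 trials with first-lick in 2-3 s")
  tt <- trials[sel, ]
  amp <- vapply(seq_len(nrow(tt)), function(i) {
    lick <- tt$cue_time[i] + tt$first_lick_time[i]
    b_idx <- time_index(lick - 0.6, fs):time_index(lick - 0.4, fs)
    p_idx <- time_index(lick - 0.2, fs):time_index(lick + 0.2, fs)
    max(x[p_idx]) - mean(x[b_idx])
  }, numeric(1))
  m <- mean(amp)
  if (!is.finite(m) || m == 0) abort("zero lick-transient amplitude")
  structure(100 * x / m, class = "dff_trace",
            method = attr(dff, "method"), params = attr(dff, "params"),
            lick_amplitude = m, units = "percent")
}
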