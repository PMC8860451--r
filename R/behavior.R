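#' Classify trial outcomes from first-lick latency
#'
#' Maps first-lick latencies onto the task's outcome categories using
#' half-open bins `[lo, hi)`: `reaction` before the reaction cutoff, `early`
#' from the cutoff to the criterion time, `reward` from the criterion to the
#' trial end, `iti_lick` from trial end to the end of the intertrial interval,
#' and `no_lick` when no lick occurred. A lick exactly at the criterion time is
#' rewarded.
#'
#' @param first_lick Numeric latencies, seconds post-cue (`NA` = no lick).
#' @param cfg A [task_config()].
#' @return Factor with levels reaction/early/reward/iti_lick/no_lick.
#' @export
#' @examples
#' classify_outcome(c(0.4, 3.2, 3.4, 8, NA), task_config())
classify_outcome <- function(first_lick, cfg = task_config()) {
  if (any(first_lick < 0, na.rm = TRUE)) abort("negative first-lick time")
  lv <- c("reaction", "early", "reward", "iti_lick", "no_lick")
  out <- rep("no_lick", length(first_lick))
  t <- first_lick
  out[!is.na(t) & t < cfg$reaction_cutoff] <- "reaction"
  out[!is.na(t) & t >= cfg$reaction_cutoff & t < cfg$criterion_time] <- "early"
  out[!is.na(t) & t >= cfg$criterion_time & t < cfg$trial_end] <- "reward"
  out[!is.na(t) & t >= cfg$trial_end] <- "iti_lick"
  factor(out, levels = lv)
}

#' First-lick timing histogram
#'
#' Bins first-lick latencies into fixed-width bins (default 250 ms) from zero
#' to the end of the intertrial interval.
#'
#' @param first_lick Latencies in seconds (NAs dropped).
#' @param bin_width Bin width in seconds.
#' @param t_max Upper edge of the last bin; defaults to cover all licks.
#' @return A tibble of class `timing_histogram`: `bin_lo`, `bin_hi`,
#'   `bin_center`, `count`, with attribute `n_trials`.
#' @export
timing_histogram <- function(first_lick, bin_width = 0.25, t_max = NULL) {
  t <- first_lick[!is.na(first_lick)]
  if (!length(t)) abort("no first-licks to bin")
  t_max <- t_max %||% (ceiling(max(t) / bin_width) * bin_width)
  edges <- seq(0, t_max, by = bin_width)
  if (max(t) >= t_max) edges <- c(edges, t_max + bin_width)
  idx <- findInterval(t, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts
  )
  new_ramptime_result(out, "timing_histogram", n_trials = length(first_lick))
}

#' Hazard function of a timing histogram
#'
#' Corrects the survival bias of response-time histograms by dividing the
#' count in each bin by the number of response opportunities remaining at that
#' bin: the total number of first-licks occurring at that bin-time or later.
#' The result is the conditional probability of moving in a bin given that
#' movement has not yet occurred. Bins with zero remaining opportunities have
#' an undefined hazard and are reported as `NA`.
#'
#' @param hist A [timing_histogram()].
#' @return A tibble of class `hazard_curve`: `bin_center`, `count`,
#'   `opportunities`, `hazard`.
#' @export
#' @examples
#' h <- timing_histogram(c(0.3, 0.4, 0.6, 1.1), bin_width = 0.5)
#' hazard_function(h)
hazard_function <- function(hist) {
  if (sum(hist$count) == 0) abort("empty histogram")
  opp <- rev(cumsum(rev(hist$count)))
  hz <- ifelse(opp > 0, hist$count / opp, NA_real_)
  out <- tibble(
    bin_center = hist$bin_center,
    count = hist$count,
    opportunities = opp,
    hazard = hz
  )
  new_ramptime_result(out, "hazard_curve",
                      bin_width = hist$bin_hi[1] - hist$bin_lo[1])
}

#' Reconstruct a timing histogram from its hazard curve
#'
#' Inverts [hazard_function()] by the survival recursion: opportunities at the
#' first bin equal the total count, each bin's count is `hazard *
#' opportunities`, and opportunities decrease by the count. Exact for any
#' histogram, which makes it a useful integrity check.
#'
#' @param hz A `hazard_curve`.
#' @param total Total number of first-licks (opportunities at the first bin).
#' @return Numeric vector of per-bin counts.
#' @export
hazard_to_counts <- function(hz, total = hz$opportunities[1]) {
  n <- nrow(hz)
  counts <- numeric(n)
  opp <- total
  for (i in seq_len(n)) {
    h <- hz$hazard[i]
    if (is.na(h) || opp <= 0) break
    counts[i] <- h * opp
    opp <- opp - counts[i]
  }
  counts
}

#' Event-aligned average of a continuous trace
#'
#' Extracts windows of `signal` around each event, optionally grouped by a
#' per-event attribute, and returns the per-group mean with a normal 95%
#' confidence band. When `truncate_at` is supplied (per-event times on the same
#' clock), each event's trace is dropped from the average 150 ms before that
#' time, excluding peri-movement samples.
#'
#' @param signal Numeric trace sampled at `fs`.
#' @param events Event times, seconds.
#' @param window Two-element window around each event, seconds.
#' @param fs Sampling rate, Hz.
#' @param group Optional per-event grouping values (e.g. move-time bin).
#' @param truncate_at Optional per-event truncation times (seconds); samples
#'   later than `truncate_at - 0.15` are excluded.
#' @return Tibble: `group`, `t`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
event_aligned_average <- function(signal, events, window = c(-1, 4), fs,
                                  group = NULL, truncate_at = NULL) {
  group <- group %||% rep("all", length(events))
  rel <- seq(round(window[1] * fs), round(window[2] * fs)) / fs
  n_dropped <- 0L
  rows <- purrr::map(seq_along(events), function(i) {
    idx <- time_index(events[i], fs) + round(rel * fs)
    if (idx[1] < 1 || idx[length(idx)] > length(signal)) {
      n_dropped <<- n_dropped + 1L
      return(NULL)
    }
    v <- signal[idx]
    if (!is.null(truncate_at)) {
      v[events[i] + rel > truncate_at[i] - 0.15] <- NA
    }
    tibble(group = group[i], t = rel, value = v)
  })
  if (n_dropped > 0) {
    warn(sprintf("%d events dropped: window exceeds session span", n_dropped))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(group, t) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) / sqrt(pmax(n, 1)),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = mean - 1.96 * .data$se, ci_hi = mean + 1.96 * .data$se) |>
    dplyr::filter(n > 0)
  new_ramptime_result(out, "aligned_average")
}

#' Correlation of pre-cue signals with first-lick time
#'
#' Averages a dF/F trace over a pre-trial window per trial (2 s before the
#' lamp-off event, or the 0.4 s preceding the cue) and correlates it with the
#' first-lick latency across trials with latencies in 0.75-4 s. The 95%
#' confidence interval uses the Fisher z transform. Fewer than 700 usable
#' trials triggers a warning rather than an error.
#'
#' @param dff A [compute_dff()] result (or numeric trace).
#' @param trials Trial table.
#' @param window `"baseline"` (lamp-off - 2 s to lamp-off) or `"loi"` (cue -
#'   0.4 s to cue).
#' @param fs Sampling rate, Hz.
#' @param lick_range Latency range of included trials, seconds.
#' @return One-row tibble: `r`, `ci_lo`, `ci_hi`, `n`, `window`.
#' @export
baseline_timing_correlation <- function(dff, trials, window = c("baseline", "loi"),
                                        fs, lick_range = c(0.75, 4)) {
  window <- match.arg(window)
  x <- as.numeric(dff)
  keep <- !is.na(trials$first_lick_time) &
    trials$first_lick_time >= lick_range[1] &
    trials$first_lick_time <= lick_range[2]
  tt <- trials[keep, ]
  if (nrow(tt) < 700) {
    warn(sprintf("only %d trials pooled (fewer than 700)", nrow(tt)))
  }
  pred <- vapply(seq_len(nrow(tt)), function(i) {
    win <- if (window == "baseline") {
      c(tt$lampoff_time[i] - 2, tt$lampoff_time[i])
    } else {
      c(tt$cue_time[i] - 0.4, tt$cue_time[i])
    }
    idx <- max(1L, time_index(win[1], fs)):min(length(x), time_index(win[2], fs))
    mean(x[idx])
  }, numeric(1))
  if (stats::sd(pred) == 0) abort("zero-variance predictor window")
  ct <- stats::cor.test(pred, tt$first_lick_time)
  tibble(
    window = window, r = unname(ct$estimate),
    ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2], n = nrow(tt)
  )
}

#' Weber-law summary of timing distributions
#'
#' Per-target mean, SD and coefficient of variation of first-lick latencies,
#' plus the maximum pairwise CV ratio across targets (1 under exact scalar
#' timing).
#'
#' @param times_by_target Named list of latency vectors, one per target time.
#' @return List with `per_target` tibble and `max_cv_ratio` (NA for a single
#'   target).
#' @export
#' @examples
#' weber_summary(list(`3.3` = rlnorm(500, 1, .3), `5` = rlnorm(500, 1.4, .3)))
weber_summary <- function(times_by_target) {
  per <- purrr::imap(times_by_target, function(t, nm) {
    t <- t[!is.na(t)]
    tibble(target = nm, n = length(t), mean = mean(t), sd = stats::sd(t),
           cv = stats::sd(t) / mean(t))
  }) |> dplyr::bind_rows()
  ratio <- if (nrow(per) >= 2) {
    cv <- per$cv
    max(outer(cv, cv, "/"))
  } else {
    NA_real_
  }
  list(per_target = per, max_cv_ratio = ratio)
}
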