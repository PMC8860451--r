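# ---- optogenetic effect statistics ------------------------------------------

#' Two-sample Kolmogorov-Smirnov test
#'
#' Unsigned two-sample KS test of stimulated versus unstimulated first-lick
#' times: the sup-norm distance between the two empirical cdfs with the
#' asymptotic p-value (exact for small samples, with a warning below n = 5).
#'
#' @param stim,unstim First-lick times, seconds.
#' @return One-row tibble: `d`, `p`, `n_stim`, `n_unstim`.
#' @export
ks_two_sample <- function(stim, unstim) {
  stim <- stim[!is.na(stim)]
  unstim <- unstim[!is.na(unstim)]
  if (!length(stim) || !length(unstim)) abort("both samples must be non-empty")
  exact <- NULL
  if (min(length(stim), length(unstim)) < 5) {
    warn("sample smaller than 5; using exact small-sample p-value")
    exact <- TRUE
  }
  kt <- suppressWarnings(stats::ks.test(stim, unstim, exact = exact))
  tibble(d = unname(kt$statistic), p = kt$p.value,
         n_stim = length(stim), n_unstim = length(unstim))
}

#' Bootstrapped distribution shift
#'
#' Draws one stimulated and one unstimulated trial at random `n_boot` times
#' and takes the difference (stimulated minus unstimulated), giving the
#' paired-draw difference distribution; summarises it by its median or mean
#' with a percentile 95% interval. A negative shift means stimulated licks
#' are earlier.
#'
#' @param stim,unstim First-lick times.
#' @param stat `"median"` or `"mean"` of the difference distribution.
#' @param n_boot Number of paired draws.
#' @param seed Seed.
#' @return One-row tibble: `stat`, `shift`, `ci_lo`, `ci_hi`, `n_boot`.
#' @export
bootstrap_shift <- function(stim, unstim, stat = c("median", "mean"),
                            n_boot = 1e5, seed = NULL) {
  stat <- match.arg(stat)
  stim <- stim[!is.na(stim)]
  unstim <- unstim[!is.na(unstim)]
  if (length(stim) < 2 || length(unstim) < 2) abort("pools must have >= 2 trials")
  seed_rng(seed)
  diffs <- sample(stim, n_boot, replace = TRUE) -
    sample(unstim, n_boot, replace = TRUE)
  f <- if (stat == "median") stats::median else mean
  q <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  tibble(stat = stat, shift = f(diffs), ci_lo = q[1], ci_hi = q[2],
         n_boot = n_boot)
}

# signed area between the two empirical cdfs over [range], stim - unstim
dauc_stat <- function(stim, unstim, range) {
  grid <- sort(unique(c(range, stim, unstim)))
  grid <- grid[grid >= range[1] & grid <= range[2]]
  if (length(grid) < 2) return(0)
  Fs <- stats::ecdf(stim)(grid)
  Fu <- stats::ecdf(unstim)(grid)
  dt <- diff(grid)
  sum((Fs[-length(Fs)] - Fu[-length(Fu)]) * dt)
}

#' dAUC permutation test
#'
#' Integral of the difference between the stimulated and unstimulated
#' empirical cdfs over a fixed range (0.7-7 s by default). The sign
#' convention is stimulated minus unstimulated, so an early shift of the
#' stimulated distribution gives a positive dAUC (set `legacy_sign = TRUE`
#' for the opposite convention). Significance is a two-sided permutation test
#' shuffling trial identities, with the add-one p estimator
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param stim,unstim First-lick times.
#' @param range Integration range, seconds.
#' @param n_perm Number of permutations.
#' @param legacy_sign Flip the sign convention.
#' @param seed Seed.
#' @return One-row tibble: `dauc`, `p`, `n_perm`.
#' @export
dauc_permutation <- function(stim, unstim, range = c(0.7, 7), n_perm = 10000,
                             legacy_sign = FALSE, seed = NULL) {
  stim <- stim[!is.na(stim)]
  unstim <- unstim[!is.na(unstim)]
  if (!any(stim >= range[1] & stim <= range[2]) ||
      !any(unstim >= range[1] & unstim <= range[2])) {
    abort("both samples need mass inside the integration range")
  }
  seed_rng(seed)
  obs <- dauc_stat(stim, unstim, range)
  pool <- c(stim, unstim)
  n1 <- length(stim)
  # permutation distribution, vectorised over sorted pooled times
  grid <- sort(unique(c(range, pool)))
  grid <- grid[grid >= range[1] & grid <= range[2]]
  dt <- diff(grid)
  n <- length(pool)
  lab <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) lab[sample.int(n, n1), b] <- 1L
  o <- order(pool)
  ps <- pool[o]
  labs <- lab[o, , drop = FALSE]
  counts1 <- apply(labs, 2, cumsum)
  counts0 <- matrix(seq_len(n), n, n_perm) - counts1
  # cdf values just below each grid point boundary handled via findInterval
  pos <- findInterval(grid, ps)
  F1 <- rbind(0, counts1)[pos + 1L, , drop = FALSE] / n1
  F0 <- rbind(0, counts0)[pos + 1L, , drop = FALSE] / (n - n1)
  null_d <- colSums((F1[-length(grid), , drop = FALSE] -
                       F0[-length(grid), , drop = FALSE]) * dt)
  p <- (sum(abs(null_d) >= abs(obs)) + 1) / (n_perm + 1)
  sign <- if (legacy_sign) -1 else 1
  tibble(dauc = sign * obs, p = p, n_perm = n_perm)
}

#' Full per-session optogenetic comparison
#'
#' Runs the KS test, bootstrapped median and mean shifts, and the dAUC
#' permutation test on one session's stimulated and unstimulated first-lick
#' pools.
#'
#' @param trials Trial table with `first_lick_time` and `opto_on`.
#' @param n_boot Paired bootstrap draws.
#' @param n_perm dAUC permutations.
#' @param category Optional label (`"activation"`, `"inhibition"`,
#'   `"no_opsin"`).
#' @param seed Seed.
#' @return One-row tibble of class `opto_comparison` with all statistics.
#' @export
opto_comparison <- function(trials, n_boot = 1e5, n_perm = 10000,
                            category = NA_character_, seed = 1) {
  stim <- trials$first_lick_time[trials$opto_on]
  unstim <- trials$first_lick_time[!trials$opto_on]
  ks <- ks_two_sample(stim, unstim)
  bs_med <- bootstrap_shift(stim, unstim, "median", n_boot, seed = seed)
  bs_mean <- bootstrap_shift(stim, unstim, "mean", n_boot, seed = seed + 1)
  da <- dauc_permutation(stim, unstim, n_perm = n_perm, seed = seed + 2)
  out <- tibble(
    category = category,
    ks_d = ks$d, ks_p = ks$p,
    d_median = bs_med$shift, d_median_lo = bs_med$ci_lo,
    d_median_hi = bs_med$ci_hi,
    d_mean = bs_mean$shift, d_mean_lo = bs_mean$ci_lo,
    d_mean_hi = bs_mean$ci_hi,
    dauc = da$dauc, dauc_p = da$p,
    n_stim = ks$n_stim, n_unstim = ks$n_unstim
  )
  new_ramptime_result(out, "opto_comparison")
}
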