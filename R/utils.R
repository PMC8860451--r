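#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# index of time t (seconds) on a grid sampled at fs starting at t = 0
time_index <- function(t, fs) as.integer(round(t * fs)) + 1L

# centred moving average with the window shrunk symmetrically at the edges,
# computed from a cumulative sum; half is the half-width in samples
moving_average_centered <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  lo <- i - h
  hi <- i + h
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# zero-phase Gaussian smoothing, kernel truncated at +/- 3 sigma
gaussian_smooth <- function(x, sigma_s, fs) {
  sigma <- sigma_s * fs
  if (sigma < 0.5) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(rep(NA_real_, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

inv_logit <- function(x) 1 / (1 + exp(-x))

# deterministic seeding: functions taking `seed` call this once on entry
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# linear interpolation of a trace onto `n_out` evenly spaced points
interp_to_length <- function(x, n_out) {
  n <- length(x)
  if (n == n_out) return(x)
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq(0, 1, length.out = n), x, xout = seq(0, 1, length.out = n_out))$y
}

new_ramptime_result <- function(x, class, ...) {
  structure(x, class = c(class, class(x)), ...)
}
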