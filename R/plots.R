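#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_col geom_point
#'   geom_ribbon geom_step labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a hazard curve
#'
#' Bars for the per-bin conditional movement probability; undefined bins
#' (zero remaining opportunities) are masked.
#'
#' @param object A `hazard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hazard_curve <- function(object, ...) {
  d <- object[!is.na(object$hazard), ]
  ggplot(d, aes(x = .data$bin_center, y = .data$hazard)) +
    geom_col(width = attr(object, "bin_width") * 0.9, fill = "grey30") +
    labs(x = "time from cue (s)", y = "hazard (P(move | not yet moved))") +
    theme_minimal()
}

#' Plot event-aligned averages
#'
#' @param object An `aligned_average`.
#' @param ... Unused.
#' @return A ggplot with one ribboned trace per group.
#' @export
autoplot.aligned_average <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$mean, colour = factor(.data$group),
                     fill = factor(.data$group))) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), alpha = 0.2,
                colour = NA) +
    geom_line() +
    labs(x = "time from event (s)", y = "signal", colour = "group",
         fill = "group") +
    theme_minimal()
}

#' Plot the nest ledger of a nested fit
#'
#' Held-out loss by nest, annotated with the input added at each nest.
#'
#' @param object A `nested_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nested_fit <- function(object, ...) {
  ggplot(object$nests, aes(x = .data$nest, y = .data$test_loss)) +
    geom_line() + geom_point() +
    ggplot2::geom_text(aes(label = .data$input), vjust = -0.8, size = 3) +
    labs(x = "nest", y = "held-out loss") +
    theme_minimal()
}

#' Plot a distortion-index profile
#'
#' @param object A `distortion_profile`.
#' @param ... Unused.
#' @return A ggplot of the smoothed distortion index over the pair window.
#' @export
autoplot.distortion_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$di_smooth)) +
    geom_line() +
    labs(x = "time from pair cue (s)", y = "distortion index") +
    theme_minimal()
}

#' Plot fitted versus empirical hazard
#'
#' @param object A `fitted_hazard`.
#' @param ... Unused.
#' @return A ggplot comparing the normalised fitted and empirical hazards.
#' @export
autoplot.fitted_hazard <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curves[, c("bin_center", "fitted_norm",
                                             "empirical_norm")],
                           -"bin_center", names_to = "which",
                           values_to = "hazard")
  ggplot(d, aes(x = .data$bin_center, y = .data$hazard,
                colour = .data$which)) +
    geom_step() +
    labs(x = "time from cue (s)", y = "normalised hazard",
         subtitle = sprintf("R² = %.2f", object$r_squared)) +
    theme_minimal()
}

#' Plot first-lick cdfs of stimulated and unstimulated trials
#'
#' @param trials Trial table with `first_lick_time` and `opto_on`.
#' @return A ggplot of the two empirical cdfs.
#' @export
plot_opto_cdf <- function(trials) {
  d <- trials[!is.na(trials$first_lick_time), ]
  ggplot(d, aes(x = .data$first_lick_time,
                colour = ifelse(.data$opto_on, "stimulated", "unstimulated"))) +
    ggplot2::stat_ecdf() +
    labs(x = "first-lick time (s)", y = "cumulative probability",
         colour = NULL) +
    theme_minimal()
}
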