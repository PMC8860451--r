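#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a nested ridge fit
#'
#' One row per coefficient of the requested (default final) nest.
#'
#' @param x A `nested_fit`.
#' @param nest 0-based nest index; default final.
#' @param ... Unused.
#' @return Tibble: `nest`, `term`, `estimate`.
#' @export
tidy.nested_fit <- function(x, nest = NULL, ...) {
  j <- if (is.null(nest)) length(x$coefficients) else nest + 1L
  co <- x$coefficients[[j]]
  tibble(nest = j - 1L, term = names(co), estimate = unname(co))
}

#' @rdname tidy.nested_fit
#' @export
glance.nested_fit <- function(x, ...) {
  last <- x$nests[nrow(x$nests), ]
  tibble(
    n_nests = nrow(x$nests),
    n_predictors = last$n_predictors,
    lambda = last$lambda,
    train_loss = last$train_loss,
    test_loss = last$test_loss,
    r_squared = last$r_squared,
    aic = last$aic, bic = last$bic
  )
}

#' Tidy a movement-state fit
#'
#' @param x A `state_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (`nest`, `term`, `estimate`, `sd`).
#' @export
tidy.state_fit <- function(x, ...) x$coefficients

#' @rdname tidy.state_fit
#' @export
glance.state_fit <- function(x, ...) {
  tibble(n_nests = max(x$coefficients$nest), n_boot = x$n_boot,
         n_state_points = sum(x$series$state))
}

#' Tidy an optogenetic comparison
#'
#' @param x An `opto_comparison`.
#' @param ... Unused.
#' @return Long tibble: `statistic`, `value`.
#' @export
tidy.opto_comparison <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("ks_d", "ks_p", "d_median", "d_mean",
                                       "dauc", "dauc_p")],
                      dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}
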