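#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chamber decay fit
#'
#' @param x A `tau_fit` from [estimate_tau()].
#' @param ... Unused.
#' @return A one-row tibble with `tau`, `fc`, `log_slope`, `intercept`,
#'   `n` (fitted samples) and `r_squared`.
#' @export
tidy.tau_fit <- function(x, ...) {
  # noiseless synthetic decays fit perfectly; the usual lm caveat is moot
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(tau = x$tau, fc = x$fc,
                 log_slope = stats::coef(x$fit)[[2]],
                 intercept = stats::coef(x$fit)[[1]],
                 n = length(x$segment), r_squared = s$r.squared)
}

#' @rdname tidy.tau_fit
#' @export
glance.tau_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, fc = x$fc, n = length(x$segment),
                 sigma = suppressWarnings(summary(x$fit))$sigma)
}

#' Tidy a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A one-row tibble with `kind`, `gain` and `offset`.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, gain = x$gain, offset = x$offset)
}

#' Summarise an analysed recording
#'
#' @param x A `wbp_analysis` from [analyze_breathing()].
#' @param ... Unused.
#' @return A one-row tibble with the number of breaths, respiratory rate,
#'   median raw and adjusted tidal volumes and the adjustment factor.
#' @export
glance.wbp_analysis <- function(x, ...) {
  tibble::tibble(
    n_breaths = nrow(x$breaths),
    f_r = if (nrow(x$breaths)) x$breaths$f_r[1] else NA_real_,
    v_t_ul = stats::median(x$breaths$v_t_ul),
    adj_v_t_ul = stats::median(x$breaths$adj_v_t_ul),
    f_adj = if (!is.null(x$adjustment)) x$adjustment$F_adj else NA_real_)
}
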