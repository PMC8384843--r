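#' Zero-phase band-pass filter
#'
#' Offline noise reduction applied to the raw chamber flow/pressure signal:
#' a 2nd-order Butterworth band-pass run forward and backward
#' (`signal::filtfilt`), giving zero phase shift so that timing comparisons
#' between channels stay valid. Default band 0.5-20 Hz.
#'
#' @param trace A tibble with a `time` column and the signal column.
#' @param lo,hi Band edges \[Hz\], `0 < lo < hi < fs/2`.
#' @param col Name of the signal column; defaults to the first non-time
#'   column.
#' @return The trace with the signal column filtered (DC removed).
#' @export
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' tr <- tibble::tibble(time = t, x = sin(2 * pi * 5 * t))
#' filtered <- bandpass(tr)
bandpass <- function(trace, lo = 0.5, hi = 20, col = NULL) {
  col <- .value_col(trace, col)
  fs <- trace_fs(trace)
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("Band must satisfy 0 < lo < hi < fs/2.", call. = FALSE)
  }
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- trace[[col]]
  trace[[col]] <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  trace
}

#' Two-point flow calibration
#'
#' In flow mode the chamber wall acts as a pneumotach whose signal is
#' calibrated against two known flows (typically bias flow off and on).
#' The fitted model is `flow = gain * (raw - offset)`.
#'
#' @param raw1,raw2 Raw sensor readings at the two known flows.
#' @param flow1,flow2 The two known flows (any consistent unit, e.g.
#'   mL min^-1).
#' @return A one-row tibble of class `calibration_model` with columns
#'   `gain`, `offset`, `kind = "flow"`.
#' @export
#' @examples
#' two_point_flow_calibration(0, 0, 1, 150)
two_point_flow_calibration <- function(raw1, flow1, raw2, flow2) {
  if (flow1 == flow2) stop("The two calibration flows must differ.", call. = FALSE)
  if (raw1 == raw2) {
    stop("Degenerate calibration: identical raw readings at different flows.",
         call. = FALSE)
  }
  gain <- (flow2 - flow1) / (raw2 - raw1)
  offset <- raw1 - flow1 / gain
  out <- tibble::tibble(gain = gain, offset = offset, kind = "flow")
  class(out) <- c("calibration_model", class(out))
  out
}

#' Apply a linear calibration model to a trace
#'
#' @param trace A tibble with a `time` column and a raw signal column.
#' @param model A `calibration_model`.
#' @param col Signal column name; defaults to the first non-time column.
#' @return The trace with the column mapped to physical units
#'   (`gain * (raw - offset)`).
#' @export
apply_calibration <- function(trace, model, col = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  col <- .value_col(trace, col)
  trace[[col]] <- model$gain * (trace[[col]] - model$offset)
  trace
}

#' Integrate a flow trace with cycle reset
#'
#' Cumulative trapezoidal integral of the flow, reset to zero at every
#' sample where the flow crosses from non-positive to positive (the
#' acquisition software's "reset each cycle" integral semantics). The reset
#' sample indices are attached as attribute `"resets"`.
#'
#' @param trace A tibble with `time` and a flow column.
#' @param col Flow column name; defaults to the first non-time column.
#' @return A tibble with columns `time` and `volume` (flow units times
#'   seconds).
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' tr <- tibble::tibble(time = t, flow = sin(2 * pi * t))
#' vol <- integrate_with_reset(tr)
integrate_with_reset <- function(trace, col = NULL) {
  col <- .value_col(trace, col)
  f <- trace[[col]]
  t <- trace$time
  n <- length(f)
  cum <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(t)))
  resets <- which(f > 0 & dplyr::lag(f, default = 1) <= 0)
  base <- rep(0, n)
  if (length(resets) > 0) {
    carry <- c(0, cum[resets])
    base <- carry[findInterval(seq_len(n), resets) + 1L]
  }
  out <- tibble::tibble(time = t, volume = cum - base)
  attr(out, "resets") <- resets
  out
}

#' Closed-chamber volume calibration from a syringe step
#'
#' In the closed (barometric) mode the pressure signal is calibrated by
#' injecting or withdrawing a known volume (500 uL by default in the
#' emulated rig) and measuring the resulting pressure step as the
#' difference of pre- and post-step medians.
#'
#' @param trace A tibble with `time` and the pressure column.
#' @param injected_volume Injected (or withdrawn) volume \[uL\], `> 0`.
#' @param step_time Time \[s\] of the injection; located automatically at
#'   the largest absolute one-sample difference when `NULL`.
#' @param window Length \[s\] of the pre/post median windows.
#' @param guard Guard interval \[s\] excluded around the step.
#' @param noise_k Detectability requirement: the step amplitude must exceed
#'   `noise_k` times the pre-window standard deviation.
#' @param col Pressure column name; defaults to the first non-time column.
#' @return A one-row tibble of class `calibration_model` with columns
#'   `gain` \[uL per sensor unit\], `offset` (pre-step baseline), `kind =
#'   "volume"`, `step` (measured step amplitude, sensor units).
#' @export
closed_chamber_volume_calibration <- function(trace, injected_volume = 500,
                                              step_time = NULL, window = 0.2,
                                              guard = 0.05, noise_k = 3,
                                              col = NULL) {
  stopifnot(injected_volume > 0)
  col <- .value_col(trace, col)
  x <- trace[[col]]
  t <- trace$time
  fs <- trace_fs(trace)
  if (is.null(step_time)) {
    step_time <- t[which.max(abs(diff(x))) + 1]
  }
  pre <- x[t >= step_time - guard - window & t < step_time - guard]
  post <- x[t > step_time + guard & t <= step_time + guard + window]
  if (length(pre) < 3 || length(post) < 3) {
    stop("Not enough samples around the step for the median windows.",
         call. = FALSE)
  }
  step <- stats::median(post) - stats::median(pre)
  floor_sd <- stats::sd(pre)
  if (abs(step) <= noise_k * floor_sd) {
    stop("No detectable step: amplitude below the noise floor.", call. = FALSE)
  }
  out <- tibble::tibble(gain = injected_volume / abs(step),
                        offset = stats::median(pre), kind = "volume",
                        step = step)
  class(out) <- c("calibration_model", class(out))
  out
}

#' Estimate the chamber time constant from an occlusion-release decay
#'
#' The chamber's low-pass time constant is measured by occluding the air
#' inlet, letting pressure build, releasing, and fitting the exponential
#' decay. The fit is log-linear least squares on the segment between
#' `fit_range[1]` and `fit_range[2]` of the peak (defaults 90% to 10%),
#' which avoids the release transient and the noise floor.
#'
#' @param trace A tibble with `time` and the decaying pressure column; the
#'   trace should start at or near the release peak.
#' @param fit_range Upper and lower fractions of the peak delimiting the
#'   fitted segment.
#' @param col Pressure column name; defaults to the first non-time column.
#' @return An object of class `tau_fit` with elements `tau` \[s\], `fc`
#'   \[s^-1\], `fit` (the underlying `lm`), `segment` (fitted sample
#'   indices) and `data`. Supports [generics::tidy()], [generics::glance()]
#'   and `autoplot()`.
#' @export
#' @examples
#' t <- seq(0, 0.5, by = 1e-3)
#' fit <- estimate_tau(tibble::tibble(time = t, p = exp(-t / 0.058)))
#' fit$tau
estimate_tau <- function(trace, fit_range = c(0.9, 0.1), col = NULL) {
  stopifnot(length(fit_range) == 2, fit_range[1] > fit_range[2],
            fit_range[2] > 0, fit_range[1] < 1)
  col <- .value_col(trace, col)
  x <- trace[[col]]
  t <- trace$time
  i_peak <- which.max(x)
  peak <- x[i_peak]
  if (!is.finite(peak) || peak <= 0) {
    stop("Decay fit failed: no positive peak.", call. = FALSE)
  }
  after <- seq(i_peak, length(x))
  i_hi <- after[which(x[after] <= fit_range[1] * peak)[1]]
  i_lo <- after[which(x[after] <= fit_range[2] * peak)[1]]
  if (is.na(i_hi) || is.na(i_lo) || i_lo - i_hi < 5) {
    stop("Decay fit failed: trace does not decay through the fit range.",
         call. = FALSE)
  }
  seg <- seq(i_hi, i_lo)
  y <- x[seg]
  if (any(y <= 0)) {
    stop("Decay fit failed: non-positive values inside the fit segment.",
         call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ t[seg])
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) stop("Decay fit failed: signal is not decaying.", call. = FALSE)
  structure(list(tau = -1 / slope, fc = corner_frequency(-1 / slope),
                 fit = fit, segment = seg,
                 data = tibble::tibble(time = t, value = x)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("Chamber decay fit: tau = %.4g s (fc = %.3g s^-1), %d samples\n",
              x$tau, x$fc, length(x$segment)))
  invisible(x)
}

#' Segment a volume trace into breaths
#'
#' Splits the reset-integrated volume trace into reset-to-reset windows,
#' one per breath, and reports the per-cycle tidal volume (the maximum of
#' the volume within the window; ties broken to the earliest sample) and
#' the respiratory rate from the cycle starts. Spans whose peak is below
#' `min_peak_frac` of the largest peak (integrator restarts on small
#' late-cycle flow wiggles) are merged into the preceding breath.
#'
#' @param volume A tibble from [integrate_with_reset()] (or with `time` and
#'   a volume column plus a `"resets"` attribute / `resets` argument).
#' @param resets Optional reset sample indices; defaults to the trace's
#'   `"resets"` attribute, else samples where the volume leaves zero
#'   upward.
#' @param min_peak_frac Merge threshold as a fraction of the largest
#'   per-span peak.
#' @param col Volume column name; defaults to the first non-time column.
#' @return A tibble with one row per breath: `cycle`, `t_start`, `t_end`,
#'   `t_peak`, `i_start`, `i_end`, `i_peak`, `v_t` (volume units) and
#'   `f_r` \[min^-1\] (common to all rows; 60 / mean cycle period). Zero
#'   detected cycles yield an empty tibble.
#' @export
segment_breaths <- function(volume, resets = NULL, min_peak_frac = 0.1,
                            col = NULL) {
  col <- .value_col(volume, col)
  v <- volume[[col]]
  t <- volume$time
  if (is.null(resets)) resets <- attr(volume, "resets")
  if (is.null(resets)) {
    resets <- which(v > 0 & dplyr::lag(v, default = 1) <= 0)
  }
  empty <- tibble::tibble(cycle = integer(), t_start = numeric(),
                          t_end = numeric(), t_peak = numeric(),
                          i_start = integer(), i_end = integer(),
                          i_peak = integer(), v_t = numeric(),
                          f_r = numeric())
  if (length(resets) < 1) return(empty)
  starts <- resets
  ends <- c(resets[-1] - 1L, length(v))
  peaks <- purrr::map_dbl(seq_along(starts),
                          function(k) max(v[starts[k]:ends[k]]))
  keep <- peaks >= min_peak_frac * max(peaks)
  if (!any(keep)) return(empty)
  # merge sub-threshold spans into the preceding kept breath
  grp <- cummax(ifelse(keep, seq_along(starts), 0L))
  valid <- grp > 0
  starts2 <- starts[sort(unique(grp[valid]))]
  ends2 <- purrr::map_int(sort(unique(grp[valid])),
                          function(g) max(ends[valid][grp[valid] == g]))
  i_peak <- purrr::map_int(seq_along(starts2), function(k) {
    w <- starts2[k]:ends2[k]
    w[which.max(v[w])]
  })
  f_r <- if (length(starts2) > 1) 60 / mean(diff(t[starts2])) else NA_real_
  tibble::tibble(cycle = seq_along(starts2), t_start = t[starts2],
                 t_end = t[ends2], t_peak = t[i_peak],
                 i_start = as.integer(starts2), i_end = as.integer(ends2),
                 i_peak = i_peak, v_t = v[i_peak], f_r = f_r)
}

#' Adjust tidal volume for temperature and humidity
#'
#' Scales the raw conditioning-driven tidal volume by the Drorbaugh-Fenn
#' factor: `adjV_T = F_adj * V_T`.
#'
#' @param v_t Raw tidal volume(s) \[uL\].
#' @param adj A [conditioning_adjustment()] (or a single numeric `F_adj`).
#' @return Adjusted tidal volume(s) \[uL\].
#' @export
adjust_tidal_volume <- function(v_t, adj) {
  f <- if (inherits(adj, "conditioning_adjustment")) adj$F_adj else adj
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f))
  if (any(v_t < 0)) stop("Tidal volume must be non-negative.", call. = FALSE)
  f * v_t
}

# resolve the signal column of a trace tibble
.value_col <- function(trace, col) {
  if (!is.data.frame(trace) || !"time" %in% names(trace)) {
    stop("Expected a trace tibble with a `time` column.", call. = FALSE)
  }
  if (is.null(col)) {
    cand <- setdiff(names(trace), "time")
    if (length(cand) < 1) stop("Trace has no signal column.", call. = FALSE)
    return(cand[[1]])
  }
  if (!col %in% names(trace)) {
    stop(sprintf("Column `%s` not found in trace.", col), call. = FALSE)
  }
  col
}
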