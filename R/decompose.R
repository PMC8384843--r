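#' Average a trace over cycle-locked epochs
#'
#' Pointwise mean over consecutive cycle-length epochs, using the servo
#' protocol's timing for the epoch boundaries. Used before trace
#' subtraction and Penh analysis, mirroring the practice of averaging 3-10
#' consecutive respiratory cycles. In closed mode the slowly drifting
#' baseline can be removed per epoch (`detrend = "baseline"` subtracts each
#' epoch's starting value).
#'
#' @param trace A tibble with `time` and a signal column.
#' @param protocol A [servo_protocol()] (for `cycle_period`), or supply
#'   `cycle_period` directly.
#' @param cycle_period Epoch length \[s\].
#' @param n_min Minimum number of complete cycles required.
#' @param discard Number of leading cycles to drop (start-up transient).
#' @param detrend `"none"` or `"baseline"` (subtract each epoch's first
#'   sample before averaging).
#' @param col Signal column name; defaults to the first non-time column.
#' @return A tibble with `time` (one cycle, starting at 0) and the averaged
#'   signal column; attribute `"n_cycles"` records how many epochs entered
#'   the mean.
#' @export
cycle_average <- function(trace, protocol = NULL,
                          cycle_period = protocol$cycle_period, n_min = 3,
                          discard = 0, detrend = c("none", "baseline"),
                          col = NULL) {
  detrend <- match.arg(detrend)
  if (is.null(cycle_period) || cycle_period <= 0) {
    stop("Provide a `protocol` or a positive `cycle_period`.", call. = FALSE)
  }
  col <- .value_col(trace, col)
  fs <- trace_fs(trace)
  n_per <- round(cycle_period * fs)
  x <- trace[[col]]
  n_cycles <- floor(length(x) / n_per) - discard
  if (n_cycles < n_min) {
    stop(sprintf("Insufficient data: %d complete cycles available, %d required.",
                 max(n_cycles, 0), n_min), call. = FALSE)
  }
  idx0 <- discard * n_per
  m <- matrix(x[idx0 + seq_len(n_cycles * n_per)], nrow = n_per)
  if (detrend == "baseline") m <- sweep(m, 2, m[1, ])
  out <- tibble::tibble(time = (seq_len(n_per) - 1) / fs,
                        value = rowMeans(m))
  names(out)[2] <- col
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Isolate the conditioning component by trace subtraction
#'
#' Subtracts the unheated recording from the heated recording of the same
#' protocol, after aligning the two traces by cross-correlation within a
#' small lag bound. With both pressure components present (conditioning +
#' resistance), the difference isolates the conditioning-driven pressure
#' change.
#'
#' @param hot,cold Cycle-locked traces (tibbles with `time` and a signal
#'   column) at the same sampling rate.
#' @param max_lag Alignment bound \[samples\] (10 ms at 1 kHz by default).
#' @param tie_tol Lags whose correlation comes within `tie_tol` (default 0.02) of the
#'   maximum are treated as ties and the smallest lag magnitude wins, so
#'   cycle-locked pairs are not nudged off zero by slow asymmetric
#'   components.
#' @param col Signal column name; defaults to the first non-time column of
#'   `hot`.
#' @return A tibble with `time` and the difference signal over the aligned
#'   overlap; attribute `"lag"` records the applied shift \[samples\]
#'   (positive: `cold` was delayed relative to `hot`).
#' @export
align_and_subtract <- function(hot, cold, max_lag = 10, tie_tol = 0.02,
                               col = NULL) {
  col <- .value_col(hot, col)
  col_cold <- .value_col(cold, NULL)
  fs_h <- trace_fs(hot)
  fs_c <- trace_fs(cold)
  if (abs(fs_h - fs_c) > 1e-6 * fs_h) {
    stop("Traces have incompatible sampling rates.", call. = FALSE)
  }
  x <- hot[[col]]
  y <- cold[[col_cold]]
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  lags <- seq(-max_lag, max_lag)
  score <- purrr::map_dbl(lags, function(L) {
    if (L >= 0) {
      xs <- x[(1 + L):n]; ys <- y[1:(n - L)]
    } else {
      xs <- x[1:(n + L)]; ys <- y[(1 - L):n]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(-Inf)
    stats::cor(xs, ys)
  })
  near <- which(score >= max(score) - tie_tol)
  lag <- lags[near[which.min(abs(lags[near]))]]      # ties -> smallest |lag|
  if (!is.finite(max(score))) lag <- 0L
  if (lag >= 0) {
    idx_x <- (1 + lag):n; idx_y <- 1:(n - lag)
  } else {
    idx_x <- 1:(n + lag); idx_y <- (1 - lag):n
  }
  out <- tibble::tibble(time = hot$time[idx_x], value = x[idx_x] - y[idx_y])
  names(out)[2] <- col
  attr(out, "lag") <- as.integer(lag)
  out
}
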