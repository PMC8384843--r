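#' Cycle-locked breath windows from the servo protocol
#'
#' Splits the volume trace into one window per servo cycle, using the
#' protocol timing (as the acquisition software does with the servo
#' control channel). The end-inspiratory volume peak is located within
#' the mechanically active part of each cycle (ramps plus a short
#' margin), so that late conditioning rebounds of the integrated signal
#' are not mistaken for breaths.
#'
#' @param volume A volume trace tibble (`time` plus a volume column).
#' @param protocol The [servo_protocol()] that generated the recording.
#' @param peak_margin Extra time \[s\] after the expiratory ramp inside
#'   which the volume peak is searched.
#' @param col Volume column name; defaults to the first non-time column.
#' @return A breath-window tibble compatible with [compute_penh()]:
#'   `cycle`, `t_start`, `t_end`, `t_peak`, `i_start`, `i_end`, `i_peak`,
#'   `v_t`, `f_r`.
#' @export
protocol_breaths <- function(volume, protocol, peak_margin = 0.15,
                             col = NULL) {
  stopifnot(inherits(protocol, "servo_protocol"))
  col <- .value_col(volume, col)
  v <- volume[[col]]
  t <- volume$time
  fs <- trace_fs(volume)
  cp <- protocol$cycle_period
  t_active <- protocol$t_insp + protocol$t_hold_insp + protocol$t_exp +
    peak_margin
  first <- ceiling(t[1] / cp - 1e-9)
  last <- floor((t[length(t)] + 1 / fs) / cp + 1e-9) - 1
  if (last < first) {
    return(tibble::tibble(cycle = integer(), t_start = numeric(),
                          t_end = numeric(), t_peak = numeric(),
                          i_start = integer(), i_end = integer(),
                          i_peak = integer(), v_t = numeric(),
                          f_r = numeric()))
  }
  rows <- purrr::map(first:last, function(k) {
    i_start <- which(t >= k * cp)[1]
    i_end <- max(which(t < (k + 1) * cp))
    active <- which(t >= k * cp & t <= k * cp + t_active)
    i_peak <- active[which.max(v[active])]
    tibble::tibble(cycle = k, t_start = t[i_start], t_end = t[i_end],
                   t_peak = t[i_peak], i_start = as.integer(i_start),
                   i_end = as.integer(i_end), i_peak = as.integer(i_peak),
                   v_t = v[i_peak])
  })
  out <- dplyr::bind_rows(rows)
  out$cycle <- seq_len(nrow(out))
  out$f_r <- if (nrow(out) > 1) 60 / mean(diff(out$t_start)) else 60 / cp
  out
}

#' Enhanced pause (Penh) and constituent waveform metrics
#'
#' Computes, per breath, the peak inspiratory flow (PIF), peak expiratory
#' flow (PEF), expiratory time (Te: from the volume peak to the beginning
#' of the next inspiration), relaxation time (Rt: time for the volume to
#' fall by 65% of its peak-to-end-expiratory excursion, with linear
#' interpolation between samples) and
#' \deqn{Penh = (Te/Rt - 1) \cdot PEF/PIF.}
#'
#' The beginning of the next inspiration is the start of the following
#' breath window. With windows from [protocol_breaths()] this is the next
#' servo cycle onset (the recommended analysis, mirroring the use of the
#' servo control channel); with windows from [segment_breaths()] it is
#' the next positive-going zero crossing of the flow. The final breath,
#' which has no following inspiration inside the trace, is dropped. Penh
#' is dimensionless and invariant under rescaling of the signals and of
#' time.
#'
#' @param flow A tibble with `time` and a calibrated flow column (positive
#'   during inspiration).
#' @param volume The matching volume trace (same time base), typically
#'   from [integrate_with_reset()].
#' @param breaths Breath windows from [protocol_breaths()] or
#'   [segment_breaths()]; the latter is the default when no protocol is
#'   available.
#' @param col_flow,col_volume Signal column names; default to the first
#'   non-time column of each trace.
#' @return A tibble with one row per analysable breath: `cycle`, `pif`,
#'   `pef`, `te` \[s\], `rt` \[s\], `penh`, `v_t`.
#' @export
compute_penh <- function(flow, volume, breaths = segment_breaths(volume),
                         col_flow = NULL, col_volume = NULL) {
  col_flow <- .value_col(flow, col_flow)
  col_volume <- .value_col(volume, col_volume)
  f <- flow[[col_flow]]
  v <- volume[[col_volume]]
  t <- flow$time
  if (nrow(flow) != nrow(volume)) {
    stop("Flow and volume traces must share the time base.", call. = FALSE)
  }
  if (nrow(breaths) < 2) return(.penh_empty())

  rows <- purrr::map(seq_len(nrow(breaths) - 1L), function(k) {
    b <- breaths[k, ]
    onset <- breaths$i_start[k + 1L]          # beginning of next inspiration
    i_peak <- b$i_peak
    insp <- b$i_start:i_peak
    pif <- max(f[insp])
    if (!is.finite(pif) || pif <= 0) {
      stop(sprintf("Degenerate cycle %d: no positive inspiratory flow.",
                   b$cycle), call. = FALSE)
    }
    te <- t[onset] - t[i_peak]
    exp_idx <- i_peak:onset
    pef <- -min(f[exp_idx])
    if (!is.finite(pef) || pef <= 0) {
      stop(sprintf("Degenerate cycle %d: no expiratory flow.", b$cycle),
           call. = FALSE)
    }
    v_peak <- v[i_peak]
    v_end <- min(v[exp_idx])
    target <- v_peak - 0.65 * (v_peak - v_end)
    below <- which(v[exp_idx] <= target)
    if (length(below) == 0) {
      stop(sprintf("Rt undefined in cycle %d: volume never falls by 65%%.",
                   b$cycle), call. = FALSE)
    }
    ib <- exp_idx[below[1]]
    if (ib == i_peak) {
      rt <- 0
    } else {
      # linear interpolation between the bracketing samples
      v1 <- v[ib - 1L]; v2 <- v[ib]
      frac <- if (v1 == v2) 0 else (v1 - target) / (v1 - v2)
      rt <- (t[ib - 1L] + frac * (t[ib] - t[ib - 1L])) - t[i_peak]
    }
    if (rt <= 0) {
      stop(sprintf("Rt undefined in cycle %d: non-positive relaxation time.",
                   b$cycle), call. = FALSE)
    }
    tibble::tibble(cycle = b$cycle, pif = pif, pef = pef, te = te, rt = rt,
                   penh = (te / rt - 1) * (pef / pif), v_t = b$v_t)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) .penh_empty() else out
}

.penh_empty <- function() {
  tibble::tibble(cycle = integer(), pif = numeric(), pef = numeric(),
                 te = numeric(), rt = numeric(), penh = numeric(),
                 v_t = numeric())
}

#' Summarise per-breath Penh metrics
#'
#' Averaged recordings can be summarised per condition either by the mean
#' or by the median across breaths; both are reported.
#'
#' @param penh_tbl Output of [compute_penh()].
#' @return A two-row tibble (`stat = "mean"`, `"median"`) of the metric
#'   columns.
#' @export
penh_summary <- function(penh_tbl) {
  metrics <- c("pif", "pef", "te", "rt", "penh", "v_t")
  dplyr::bind_rows(
    dplyr::summarise(penh_tbl, stat = "mean",
                     dplyr::across(dplyr::all_of(metrics), mean)),
    dplyr::summarise(penh_tbl, stat = "median",
                     dplyr::across(dplyr::all_of(metrics), stats::median)))
}
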