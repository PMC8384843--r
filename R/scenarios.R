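#' Simulate one experimental condition
#'
#' Convenience wrapper assembling the lung-model, protocol and chamber
#' configurations for the standard experimental matrix: heater on/off,
#' airway resistance none/20G/27G, expiration time 100 or 800 ms, chamber
#' time constant, and recording mode.
#'
#' @param resistance `"none"`, `"20G"`, `"27G"` or a numeric resistance
#'   \[mmHg s mL^-1\].
#' @param heater_on Logical.
#' @param t_exp Expiration duration \[s\].
#' @param tau Chamber leak time constant \[s\] (flow mode).
#' @param mode `"flow"` or `"closed"`.
#' @param n_cycles Number of respiratory cycles.
#' @param fs Sampling rate \[Hz\].
#' @param ... Further arguments passed to [run_simulation()].
#' @return A `wbp_simulation` tibble.
#' @export
#' @examples
#' sim <- simulate_condition("20G", heater_on = FALSE, n_cycles = 2)
simulate_condition <- function(resistance = "none", heater_on = TRUE,
                               t_exp = 0.1, tau = 0.058,
                               mode = c("flow", "closed"), n_cycles = 8,
                               fs = 1000, ...) {
  mode <- match.arg(mode)
  alm <- alm_config(resistance = resistance, heater_on = heater_on)
  protocol <- servo_protocol(t_exp = t_exp, n_cycles = n_cycles, fs = fs)
  chamber <- if (mode == "flow") {
    chamber_config(mode = "flow", tau = tau)
  } else {
    chamber_config(mode = "closed")
  }
  run_simulation(alm, protocol, chamber, ...)
}

#' Flow calibration via the bias flow
#'
#' Emulates the two-point pneumotach calibration: the chamber signal is
#' recorded with the bias flow off (zero flow) and on (the known bias
#' flow), and the two steady levels define the linear map from sensor
#' units to flow. The calibrated flow is positive out of the chamber, so
#' the steady bias level corresponds to `-bias_flow`.
#'
#' @param chamber A flow-mode [chamber_config()].
#' @param alm An [alm_config()] supplying the resting bulb geometry (held
#'   static during calibration).
#' @param settle Settling time \[s\] simulated before reading each level.
#' @return A `calibration_model` mapping sensor units to flow
#'   \[mL min^-1\].
#' @export
calibrate_flow_from_bias <- function(chamber, alm = alm_config(),
                                     settle = 1.5) {
  stopifnot(inherits(chamber, "chamber_config"), chamber$mode == "flow")
  alm_off <- alm_config(v_max = alm$v_max, v_min = alm$v_min,
                        resistance = alm$r_aw, heater_on = FALSE)
  protocol <- servo_protocol(cycle_period = settle + 0.5, n_cycles = 1,
                             fs = 200)
  sim_on <- run_simulation(alm_off, protocol, chamber, static_bulb = TRUE)
  raw_on <- mean(sim_on$dps[sim_on$time >= settle])
  two_point_flow_calibration(raw1 = 0, flow1 = 0,
                             raw2 = raw_on, flow2 = -chamber$bias_flow)
}

#' Full breathing analysis of a flow-mode recording
#'
#' Runs the complete recording-analysis chain on a flow-mode simulation
#' (or any dps trace): flow calibration, band-pass filtering, integration
#' with cycle reset, breath segmentation, and tidal volume with the
#' temperature/humidity adjustment.
#'
#' @param sim A `wbp_simulation` from a flow-mode run (or a tibble with
#'   `time` and `dps`).
#' @param calibration A flow `calibration_model` \[mL min^-1 per unit\];
#'   computed from the simulation's own chamber configuration via
#'   [calibrate_flow_from_bias()] when omitted.
#' @param adjustment A [conditioning_adjustment()]; derived from the
#'   simulation's heater and chamber settings when omitted (only when the
#'   heater is on; otherwise the adjusted volume is `NA`).
#' @param discard_cycles Leading cycles dropped before integration
#'   (start-up transient).
#' @param band Band-pass edges \[Hz\]; `NULL` skips filtering.
#'
#' @details Breaths are delimited by the servo protocol when the recording
#'   carries one (one window per cycle, as the acquisition software does
#'   with the servo control channel); otherwise by the integrator resets
#'   via [segment_breaths()].
#' @return A list of class `wbp_analysis`: `flow` \[mL s^-1\], `volume`
#'   \[mL\], `breaths` (per-cycle tibble with `v_t_ul`, `adj_v_t_ul`,
#'   `f_r`), `calibration`, `adjustment`.
#' @export
analyze_breathing <- function(sim, calibration = NULL, adjustment = NULL,
                              discard_cycles = 3, band = c(0.5, 20)) {
  protocol <- attr(sim, "protocol")
  chamber <- attr(sim, "chamber")
  alm <- attr(sim, "alm")
  if (is.null(calibration)) {
    if (is.null(chamber)) {
      stop("Supply a `calibration` for traces without chamber metadata.",
           call. = FALSE)
    }
    calibration <- calibrate_flow_from_bias(chamber, alm)
  }
  if (is.null(adjustment) && !is.null(alm) && alm$heater_on) {
    adjustment <- conditioning_adjustment(
      T_L = alm$t_heater, T_C = chamber$t_chamber, P_A = chamber$p_atm,
      RH_C = chamber$rh_chamber)
  }
  cp <- if (!is.null(protocol)) protocol$cycle_period else NULL
  raw <- tibble::tibble(time = sim$time, dps = sim$dps)
  flow <- apply_calibration(raw, calibration, col = "dps")
  names(flow)[2] <- "flow"
  flow$flow <- flow$flow / 60 # mL/min -> mL/s
  if (!is.null(band)) flow <- bandpass(flow, band[1], band[2], col = "flow")
  if (!is.null(cp) && discard_cycles > 0) {
    flow <- dplyr::filter(flow, .data$time >= discard_cycles * cp)
  }
  volume <- integrate_with_reset(flow, col = "flow")
  breaths <- if (!is.null(protocol)) {
    protocol_breaths(volume, protocol)
  } else {
    segment_breaths(volume)
  }
  breaths$v_t_ul <- breaths$v_t * 1000
  breaths$adj_v_t_ul <- if (!is.null(adjustment)) {
    adjust_tidal_volume(breaths$v_t_ul, adjustment)
  } else {
    NA_real_
  }
  structure(list(flow = flow, volume = volume, breaths = breaths,
                 calibration = calibration, adjustment = adjustment,
                 protocol = protocol),
            class = "wbp_analysis")
}

#' @export
print.wbp_analysis <- function(x, ...) {
  cat(sprintf("Breathing analysis: %d breaths, median V_T %.1f uL",
              nrow(x$breaths), stats::median(x$breaths$v_t_ul)))
  if (!all(is.na(x$breaths$adj_v_t_ul))) {
    cat(sprintf(", median adjV_T %.1f uL", stats::median(x$breaths$adj_v_t_ul)))
  }
  cat("\n")
  invisible(x)
}

#' Penh metrics of an analysed recording
#'
#' Computes the per-breath Penh table with breath windows locked to the
#' servo protocol when the analysed recording carries one (the
#' acquisition-side equivalent of using the servo control channel), and
#' reset-based windows otherwise.
#'
#' @param analysis A `wbp_analysis` from [analyze_breathing()].
#' @param ... Passed to [compute_penh()].
#' @return Per-breath Penh tibble (see [compute_penh()]).
#' @export
penh_metrics <- function(analysis, ...) {
  stopifnot(inherits(analysis, "wbp_analysis"))
  protocol <- analysis$protocol
  breaths <- if (!is.null(protocol)) {
    protocol_breaths(analysis$volume, protocol)
  } else {
    segment_breaths(analysis$volume)
  }
  compute_penh(analysis$flow, analysis$volume, breaths = breaths, ...)
}

#' True (device) tidal volume of a simulation
#'
#' The volume that actually enters the bulb during inspiration: the airway
#' inflow integrated over each cycle's inspiratory ramp. This is the
#' ground truth the plethysmographic estimate is compared against.
#'
#' @param sim A `wbp_simulation`.
#' @param discard_cycles Leading cycles dropped.
#' @return Median per-cycle inspired volume \[uL\].
#' @export
device_tidal_volume <- function(sim, discard_cycles = 3) {
  protocol <- attr(sim, "protocol")
  stopifnot(!is.null(protocol))
  fs <- protocol$fs
  cp <- protocol$cycle_period
  cycles <- seq(discard_cycles, protocol$n_cycles - 1)
  per_cycle <- purrr::map_dbl(cycles, function(k) {
    idx <- which(sim$time >= k * cp & sim$time <= k * cp + protocol$t_insp)
    sum(sim$q_aw[idx]) / fs
  })
  stats::median(per_cycle) * 1000
}

#' Expiratory pressure peak of a closed-mode recording
#'
#' Magnitude of the negative chamber-pressure peak during expiration, read
#' from the baseline-detrended cycle average.
#'
#' @param sim A closed-mode `wbp_simulation`.
#' @param discard_cycles Leading cycles dropped from the average.
#' @return Peak magnitude \[mmHg\] (positive number).
#' @export
expiratory_pressure_peak <- function(sim, discard_cycles = 3) {
  protocol <- attr(sim, "protocol")
  stopifnot(!is.null(protocol))
  avg <- cycle_average(tibble::tibble(time = sim$time, dps = sim$dps),
                       protocol, discard = discard_cycles,
                       detrend = "baseline")
  t2 <- protocol$t_insp + protocol$t_hold_insp
  t3 <- t2 + protocol$t_exp
  win <- avg$time >= t2 & avg$time <= t3 + 0.1
  -min(avg$dps[win])
}

#' List the bundled scenarios
#'
#' @return A tibble with scenario names and one-line descriptions.
#' @export
list_scenarios <- function() {
  tibble::tibble(
    name = c("table1", "device_calibration", "component_matrix", "tau_sweep",
             "closed_mode", "penh_matrix"),
    description = c(
      "Corner frequencies for the chamber time-constant grid",
      "Closed-rig device tidal volume for expiration 100 vs 800 ms",
      "Flow-mode traces: heater on/off x resistance none/20G/27G",
      "Adjusted tidal volume across the chamber tau grid, both expirations",
      "Closed-mode expiratory pressure peaks, 20G, both expirations",
      "Penh metrics: resistance none/20G/27G x expiration 100/800 ms"))
}

#' Run a bundled scenario
#'
#' Each scenario assembles the relevant simulations and analysis steps and
#' returns traces plus a metrics table. Results are deterministic given
#' the scenario and seed; when `out_dir` is given, every trace is written
#' with [write_traces()] (with the configuration in the header) and the
#' metrics table as tab-separated text.
#'
#' @param name Scenario name (see [list_scenarios()]).
#' @param seed Seed recorded in output metadata (the default simulations
#'   are noiseless, so it affects only optional noise).
#' @param out_dir Optional output directory.
#' @param n_cycles Cycles per simulated run.
#' @return A list with elements `name`, `metrics` (a tibble) and `traces`
#'   (a named list of trace tibbles).
#' @export
run_scenario <- function(name, seed = 1L, out_dir = NULL, n_cycles = 8) {
  name <- match.arg(name, list_scenarios()$name)
  stopifnot(n_cycles >= 6) # 3 discarded as start-up transient, >= 3 analysed
  res <- switch(
    name,
    table1 = list(metrics = corner_frequency_table(), traces = list()),
    device_calibration = .scenario_device_cal(n_cycles),
    component_matrix = .scenario_components(n_cycles),
    tau_sweep = .scenario_tau_sweep(n_cycles),
    closed_mode = .scenario_closed(n_cycles),
    penh_matrix = .scenario_penh(n_cycles))
  res$name <- name
  res$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$traces)) {
      write_traces(res$traces[[nm]],
                   file.path(out_dir, paste0(name, "_", nm, ".tsv")),
                   header = list(scenario = name, seed = seed, trace = nm))
    }
    utils::write.table(res$metrics,
                       file.path(out_dir, paste0(name, "_metrics.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

# device V_T with the ALM connected to a leaky closed rig from outside
.scenario_device_cal <- function(n_cycles) {
  rig <- chamber_config(mode = "closed", tau = 1.5, bias_flow = 0)
  alm <- alm_config(heater_on = FALSE)
  gain <- .closed_rig_gain(rig, alm)
  one <- function(t_exp) {
    protocol <- servo_protocol(t_exp = t_exp, n_cycles = n_cycles)
    sim <- run_simulation(alm, protocol, rig, bulb_displaces = FALSE)
    tr <- bandpass(tibble::tibble(time = sim$time, dps = sim$dps))
    avg <- cycle_average(tr, protocol, discard = 3, detrend = "baseline")
    v_t <- gain * (max(avg$dps) - min(avg$dps))
    list(sim = sim, v_t = v_t)
  }
  r100 <- one(0.1); r800 <- one(0.8)
  list(metrics = tibble::tibble(t_exp = c(0.1, 0.8),
                                device_v_t_ul = c(r100$v_t, r800$v_t)),
       traces = list(te100 = r100$sim, te800 = r800$sim))
}

# pressure-to-volume gain of a closed rig from a 500 uL syringe step
.closed_rig_gain <- function(rig, alm) {
  protocol <- servo_protocol(cycle_period = 3, n_cycles = 1)
  cal_sim <- run_simulation(alm, protocol, rig, static_bulb = TRUE,
                            inject_times = 1.5, inject_volumes = 0.5,
                            bulb_displaces = FALSE)
  cal <- closed_chamber_volume_calibration(
    tibble::tibble(time = cal_sim$time, dps = cal_sim$dps),
    injected_volume = 500, step_time = 1.5)
  cal$gain
}

.scenario_components <- function(n_cycles) {
  grid <- tidyr::expand_grid(heater = c(TRUE, FALSE),
                             resistance = c("none", "20G", "27G"))
  traces <- list()
  rows <- purrr::pmap(grid, function(heater, resistance) {
    sim <- simulate_condition(resistance, heater_on = heater,
                              n_cycles = n_cycles)
    avg <- cycle_average(tibble::tibble(time = sim$time, dps = sim$dps),
                         attr(sim, "protocol"), discard = 3)
    nm <- paste0(resistance, "_", if (heater) "40C" else "26C")
    traces[[nm]] <<- avg
    tibble::tibble(resistance = resistance, heater = heater,
                   peak_dps = max(abs(avg$dps - stats::median(avg$dps))))
  })
  list(metrics = dplyr::bind_rows(rows), traces = traces)
}

.scenario_tau_sweep <- function(n_cycles,
                           taus = corner_frequency_table()$tau) {
  grid <- tidyr::expand_grid(tau = taus, t_exp = c(0.1, 0.8))
  rows <- purrr::pmap(grid, function(tau, t_exp) {
    sim <- simulate_condition("none", heater_on = TRUE, t_exp = t_exp,
                              tau = tau, n_cycles = n_cycles)
    an <- analyze_breathing(sim)
    tibble::tibble(tau = tau, fc = corner_frequency(tau), t_exp = t_exp,
                   v_t_ul = stats::median(an$breaths$v_t_ul),
                   adj_v_t_ul = stats::median(an$breaths$adj_v_t_ul),
                   device_v_t_ul = device_tidal_volume(sim))
  })
  list(metrics = dplyr::bind_rows(rows), traces = list())
}

.scenario_closed <- function(n_cycles) {
  grid <- tidyr::expand_grid(resistance = c("none", "20G"),
                             t_exp = c(0.1, 0.8))
  traces <- list()
  rows <- purrr::pmap(grid, function(resistance, t_exp) {
    sim <- simulate_condition(resistance, heater_on = FALSE, t_exp = t_exp,
                              mode = "closed", n_cycles = n_cycles)
    nm <- sprintf("%s_te%d", resistance, round(t_exp * 1000))
    traces[[nm]] <<- tibble::tibble(time = sim$time, dps = sim$dps)
    tibble::tibble(resistance = resistance, t_exp = t_exp,
                   exp_peak_mmHg = expiratory_pressure_peak(sim))
  })
  list(metrics = dplyr::bind_rows(rows), traces = traces)
}

.scenario_penh <- function(n_cycles) {
  grid <- tidyr::expand_grid(resistance = c("none", "20G", "27G"),
                             t_exp = c(0.1, 0.8))
  rows <- purrr::pmap(grid, function(resistance, t_exp) {
    sim <- simulate_condition(resistance, heater_on = TRUE, t_exp = t_exp,
                              n_cycles = n_cycles)
    an <- analyze_breathing(sim)
    pm <- penh_metrics(an)
    s <- penh_summary(pm)
    tibble::tibble(resistance = resistance, t_exp = t_exp,
                   pif = s$pif[s$stat == "median"],
                   pef = s$pef[s$stat == "median"],
                   te = s$te[s$stat == "median"],
                   rt = s$rt[s$stat == "median"],
                   penh_median = s$penh[s$stat == "median"],
                   penh_mean = s$penh[s$stat == "mean"])
  })
  list(metrics = dplyr::bind_rows(rows), traces = list())
}
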