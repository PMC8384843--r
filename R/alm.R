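#' Servo timing protocol for the artificial lung
#'
#' Describes the prescribed breathing pattern of the artificial lung model:
#' a linear inflation over `t_insp`, a hold at full volume, a linear
#' deflation over `t_exp`, and a hold at minimum volume until the cycle
#' period elapses. The recordings this emulates used a 0.5 s^-1 cycle rate,
#' 50 ms inspiration and either 100 or 800 ms expiration at 1 kHz sampling.
#'
#' @param t_insp Inspiration (inflation ramp) duration \[s\].
#' @param t_exp Expiration (deflation ramp) duration \[s\].
#' @param cycle_period Full cycle duration \[s\]; must be at least
#'   `t_insp + t_exp`.
#' @param n_cycles Number of cycles to simulate.
#' @param fs Sampling rate \[Hz\] of the output traces.
#' @param t_hold_insp Optional hold at full inflation between the ramps \[s\].
#' @return A list of class `servo_protocol`.
#' @export
#' @examples
#' servo_protocol(t_exp = 0.8)
servo_protocol <- function(t_insp = 0.05, t_exp = 0.1, cycle_period = 2,
                           n_cycles = 8, fs = 1000, t_hold_insp = 0) {
  stopifnot(t_insp > 0, t_exp > 0, cycle_period > 0, n_cycles >= 1, fs > 0,
            t_hold_insp >= 0)
  if (t_insp + t_hold_insp + t_exp > cycle_period) {
    stop("`t_insp + t_hold_insp + t_exp` must not exceed `cycle_period`.",
         call. = FALSE)
  }
  if (fs < 10 / min(t_insp, t_exp)) {
    stop("Sampling rate too low to resolve the ramps: need fs >= 10/min(t_insp, t_exp).",
         call. = FALSE)
  }
  structure(list(t_insp = t_insp, t_exp = t_exp, t_hold_insp = t_hold_insp,
                 cycle_period = cycle_period, n_cycles = n_cycles, fs = fs),
            class = "servo_protocol")
}

#' Artificial lung model configuration
#'
#' Geometry, airway resistance and conditioning kinetics of the simulated
#' lung: a bulb whose gas volume is prescribed between `v_min` and `v_max`,
#' connected to the chamber through a linear airway resistance, with its gas
#' warmed toward the heater temperature and humidified toward saturation
#' while the heater is on.
#'
#' Default geometry follows the physical device: total capacity ~1.7 mL with
#' a ~0.29 mL tidal excursion. The named airway resistances are effective
#' values (laminar plus unresolved turbulent/entrance contributions) chosen
#' so that the no-cannula case is essentially unobstructed while the 20G and
#' 27G cannulas retard filling on the time scale of the 50 ms inspiration
#' (`R_aw * C_bulb` of about 11 and 44 ms respectively).
#'
#' @param v_max Fully expanded bulb gas volume \[mL\].
#' @param v_min Compressed bulb gas volume \[mL\].
#' @param resistance Either one of `"none"`, `"20G"`, `"27G"` or a numeric
#'   airway resistance \[mmHg s mL^-1\].
#' @param heater_on Logical; whether the heating foil is active.
#' @param t_heater Heater set temperature \[K\] (40 C by default).
#' @param tau_thermal Warming time constant of the bulb gas \[s\].
#' @param tau_humid Humidification time constant of the bulb gas \[s\].
#' @param entrain_ratio Jet entrainment ratio (dimensionless): while the
#'   bulb expands, the inspiratory jet entrains an additional
#'   `entrain_ratio * dV/dt` of chamber air through the heated bulb, on
#'   top of the tidal inflow itself. This recruitment of dead-space and
#'   residual gas lets the device condition more air per cycle than the
#'   tidal aliquot alone - the mechanism behind the apparent tidal-volume
#'   overestimation. Set to 0 for a strictly tidal model.
#' @return A list of class `alm_config`.
#' @export
#' @examples
#' alm_config(resistance = "27G")
alm_config <- function(v_max = 1.7, v_min = 1.41, resistance = "none",
                       heater_on = TRUE, t_heater = 313.15,
                       tau_thermal = 0.025, tau_humid = 0.025,
                       entrain_ratio = 3) {
  stopifnot(v_max > v_min, v_min > 0, t_heater > 0,
            tau_thermal > 0, tau_humid > 0, entrain_ratio >= 0)
  r_aw <- airway_resistance(resistance)
  structure(list(v_max = v_max, v_min = v_min, r_aw = r_aw,
                 resistance = if (is.character(resistance)) resistance else "custom",
                 heater_on = isTRUE(heater_on), t_heater = t_heater,
                 tau_thermal = tau_thermal, tau_humid = tau_humid,
                 entrain_ratio = entrain_ratio),
            class = "alm_config")
}

#' Effective airway resistance of the named cannulas
#'
#' @param resistance `"none"`, `"20G"`, `"27G"` or a numeric value
#'   \[mmHg s mL^-1\].
#' @return Airway resistance \[mmHg s mL^-1\].
#' @export
airway_resistance <- function(resistance) {
  if (is.numeric(resistance)) {
    if (resistance < 0) stop("Airway resistance must be >= 0.", call. = FALSE)
    # a truly zero resistance makes the flow law ill-posed; the open luer
    # adapter has a small finite resistance
    return(max(resistance, 1e-4))
  }
  switch(match.arg(resistance, c("none", "20G", "27G")),
         none = 1e-4, `20G` = 5, `27G` = 20)
}

#' Prescribed bulb volume trajectory
#'
#' Piecewise-linear prescribed gas volume of the bulb: ramp `v_min -> v_max`
#' over the inspiration time, optional hold, ramp back over the expiration
#' time, hold at `v_min` until the cycle ends; exactly periodic, first
#' sample at `v_min`.
#'
#' @param protocol A [servo_protocol()].
#' @param config An [alm_config()].
#' @param fs Optional sampling rate override \[Hz\] (used internally to
#'   generate the sub-stepped trajectory).
#' @return A tibble with columns `time` \[s\] and `v_bulb` \[mL\].
#' @export
#' @examples
#' traj <- bulb_volume_trajectory(servo_protocol(n_cycles = 1), alm_config())
bulb_volume_trajectory <- function(protocol, config, fs = protocol$fs) {
  stopifnot(inherits(protocol, "servo_protocol"), inherits(config, "alm_config"))
  n <- round(protocol$n_cycles * protocol$cycle_period * fs)
  time <- (seq_len(n) - 1) / fs
  phase <- time %% protocol$cycle_period
  t1 <- protocol$t_insp
  t2 <- t1 + protocol$t_hold_insp
  t3 <- t2 + protocol$t_exp
  dv <- config$v_max - config$v_min
  v <- ifelse(phase < t1, config$v_min + dv * phase / t1,
       ifelse(phase < t2, config$v_max,
       ifelse(phase < t3, config$v_max - dv * (phase - t2) / protocol$t_exp,
              config$v_min)))
  tibble::tibble(time = time, v_bulb = v)
}

#' Flow through the airway resistance
#'
#' Linear (laminar) pressure-flow law across the cannula: flow is positive
#' into the bulb when the chamber pressure exceeds the bulb pressure.
#'
#' @param p_bulb Bulb pressure \[mmHg\].
#' @param p_chamber Chamber pressure \[mmHg\].
#' @param r_aw Airway resistance \[mmHg s mL^-1\], `> 0`.
#' @return Flow \[mL s^-1\], positive into the bulb. Vectorised.
#' @export
airway_flow <- function(p_bulb, p_chamber, r_aw) {
  if (any(r_aw <= 0)) stop("Airway resistance must be positive.", call. = FALSE)
  (p_chamber - p_bulb) / r_aw
}
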