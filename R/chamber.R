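#' Corner frequency of the chamber leak
#'
#' The chamber with its resistive air inlet behaves as a first-order RC
#' system: a pressure offset decays with time constant `tau = R * C`, and as
#' a sensor the chamber low-passes the volume signal with corner frequency
#' `fc = 1 / (2 * pi * tau)`.
#'
#' @param tau Pressure decay time constant \[s\], `> 0`. Vectorised.
#' @return Corner frequency \[s^-1\], full precision (round only for
#'   display).
#' @export
#' @examples
#' corner_frequency(0.196) # ~0.81 s^-1
corner_frequency <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be positive and finite.", call. = FALSE)
  }
  1 / (2 * pi * tau)
}

#' Corner frequencies for a set of chamber time constants
#'
#' Convenience table mapping decay time constants to corner frequencies,
#' with a display rounding to two decimals alongside the full-precision
#' value. The default grid is the tube-length series used to tune the
#' physical chamber.
#'
#' @param taus Time constants \[s\].
#' @return A tibble with columns `tau`, `fc` (full precision) and
#'   `fc_printed` (rounded to two decimals).
#' @export
#' @examples
#' corner_frequency_table()
corner_frequency_table <- function(taus = c(0.378, 0.196, 0.172, 0.143,
                                            0.103, 0.084, 0.058, 0.049,
                                            0.046, 0.040)) {
  fc <- corner_frequency(taus)
  tibble::tibble(tau = taus, fc = fc, fc_printed = round(fc, 2))
}

#' Chamber filter specification
#'
#' The leak resistance, pneumatic compliance, time constant and corner
#' frequency of the chamber are linked by `tau = R * C` and
#' `fc = 1/(2 pi tau)`. The specification is built from a requested `tau`:
#' the compliance follows from the chamber geometry (isothermal,
#' `C = V_gas / P_atm`) and the leak resistance is derived, mirroring how
#' the physical chamber's tau is tuned with tube length.
#'
#' @param tau Pressure decay time constant \[s\].
#' @param v_gas Mean chamber gas volume \[mL\] (chamber minus bulb).
#' @param p_atm Atmospheric pressure \[mmHg\].
#' @return A one-row tibble with columns `tau`, `fc`, `r_leak`
#'   \[mmHg s mL^-1\] and `c_ch` \[mL mmHg^-1\].
#' @export
chamber_filter_spec <- function(tau, v_gas, p_atm = 760) {
  stopifnot(tau > 0, v_gas > 0, p_atm > 0)
  c_ch <- v_gas / p_atm
  tibble::tibble(tau = tau, fc = corner_frequency(tau),
                 r_leak = tau / c_ch, c_ch = c_ch)
}

#' Plethysmography chamber configuration
#'
#' @param v_chamber Chamber air volume \[mL\] (1180 mL recording chamber by
#'   default).
#' @param mode `"flow"` (bias-flow / pneumotach mode) or `"closed"`
#'   (barometric mode; the leak is shut and the bias flow off).
#' @param tau Leak time constant \[s\] in flow mode (58 ms default). In
#'   closed mode the leak is absent unless `tau` is given explicitly, which
#'   models an imperfectly sealed port.
#' @param bias_flow Bias flow \[mL min^-1\] withdrawn from the chamber in
#'   flow mode.
#' @param t_chamber Chamber (wall and ambient) temperature \[K\].
#' @param rh_chamber Chamber relative humidity (fraction).
#' @param p_atm Atmospheric pressure \[mmHg\].
#' @param tau_chamber_relax Time constant \[s\] with which a quietly
#'   drifting warm plume of expelled gas relaxes to the chamber
#'   temperature.
#' @param mixing_gain Jet-mixing gain \[mL^-1\]: the expiratory jet
#'   drives chamber mixing at an intensity of
#'   `mixing_gain * |dV_bulb/dt|`, which adds to `1/tau_chamber_relax` as
#'   the cooling rate of accumulated warm gas. A fast squeeze cools the
#'   warm excess rapidly, which is what turns a fast, forced expiration
#'   into a sharp negative pressure deflection; a slow squeeze does not.
#' @param tau_turb Persistence time \[s\] of the jet-induced turbulence:
#'   the mixing intensity follows the squeeze speed with this lag, so the
#'   dump of warm gas extends briefly past the end of a fast squeeze.
#' @param wall_capacity Heat capacity of the chamber walls as a multiple
#'   of the chamber gas heat capacity. The heat that the gas sheds is
#'   absorbed by the walls, which warm slowly; in the sealed (closed)
#'   configuration with the heater on this makes the baseline pressure
#'   ratchet upward across cycles, as observed, until the calibration
#'   valve is opened.
#' @return A list of class `chamber_config`.
#' @export
#' @examples
#' chamber_config(mode = "closed")
chamber_config <- function(v_chamber = 1180, mode = c("flow", "closed"),
                           tau = if (match.arg(mode) == "flow") 0.058 else Inf,
                           bias_flow = if (match.arg(mode) == "flow") 150 else 0,
                           t_chamber = 299.15, rh_chamber = 0.5,
                           p_atm = 760, tau_chamber_relax = 2,
                           mixing_gain = 20, tau_turb = 0.1,
                           wall_capacity = 300) {
  mode <- match.arg(mode)
  stopifnot(v_chamber > 0, bias_flow >= 0, t_chamber > 0,
            rh_chamber >= 0, rh_chamber <= 1, p_atm > 0,
            tau_chamber_relax > 0, mixing_gain >= 0, tau_turb > 0,
            wall_capacity >= 1, tau > 0)
  structure(list(v_chamber = v_chamber, mode = mode, tau = tau,
                 bias_flow = bias_flow, t_chamber = t_chamber,
                 rh_chamber = rh_chamber, p_atm = p_atm,
                 tau_chamber_relax = tau_chamber_relax,
                 mixing_gain = mixing_gain, tau_turb = tau_turb,
                 wall_capacity = wall_capacity),
            class = "chamber_config")
}
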