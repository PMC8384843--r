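#' Physical constants used throughout the package
#'
#' All internal computations use mmHg for pressure, mL for volume, K for
#' temperature, s for time and mol for amount of gas. The ideal gas constant
#' in these units is returned by `gas_constant()`.
#'
#' @return A named list with elements `R_gas` (mmHg mL mol^-1 K^-1),
#'   `P_standard` (760 mmHg) and `T_zero` (273.15 K).
#' @export
#' @examples
#' gas_constant()$R_gas
gas_constant <- function() {
  list(R_gas = 62363.67, P_standard = 760, T_zero = 273.15)
}

#' Saturation vapor pressure of water
#'
#' Magnus-form closed formula (Arden Buck coefficients over liquid water),
#' converted to mmHg. Accurate to a few tenths of a percent between 0 and
#' 60 degrees C and within 1% up to the boiling point, which is what the
#' heated-bulb / chamber temperature range requires.
#'
#' @param temperature_K Temperature in kelvin. Vectorised. Must lie in
#'   (233, 373.65) K; values outside raise an error.
#' @return Saturation vapor pressure in mmHg, same length as `temperature_K`.
#' @export
#' @examples
#' saturation_vapor_pressure(310.15) # body temperature, ~47 mmHg
saturation_vapor_pressure <- function(temperature_K) {
  if (!is.numeric(temperature_K) || anyNA(temperature_K)) {
    stop("`temperature_K` must be numeric and non-missing.", call. = FALSE)
  }
  if (any(temperature_K <= 233 | temperature_K >= 373.65)) {
    stop("`temperature_K` out of supported range (233, 373.65) K.", call. = FALSE)
  }
  t <- temperature_K - 273.15
  6.1121 * exp((18.678 - t / 234.5) * t / (257.14 + t)) * 0.75006168
}

#' Conditioning adjustment inputs
#'
#' Bundles the five quantities entering the Drorbaugh-Fenn volume adjustment:
#' atmospheric pressure, water vapor pressure in the lung and in the chamber,
#' and the lung and chamber temperatures. By default the lung is assumed
#' saturated at its temperature (`Pv_L = saturation_vapor_pressure(T_L)`) and
#' the chamber holds a given relative humidity.
#'
#' @param T_L Lung (or heated-bulb) gas temperature \[K\].
#' @param T_C Chamber gas temperature \[K\].
#' @param P_A Atmospheric pressure \[mmHg\].
#' @param Pv_L Water vapor pressure in the lung \[mmHg\]; default saturation
#'   at `T_L`.
#' @param Pv_C Water vapor pressure in the chamber \[mmHg\]; default
#'   `RH_C * saturation_vapor_pressure(T_C)`.
#' @param RH_C Chamber relative humidity (fraction), used only when `Pv_C`
#'   is not supplied.
#' @return A one-row tibble of class `conditioning_adjustment` with columns
#'   `P_A`, `Pv_L`, `Pv_C`, `T_L`, `T_C`, `F_adj`.
#' @export
#' @examples
#' conditioning_adjustment(T_L = 313.15, T_C = 299.15)
conditioning_adjustment <- function(T_L, T_C, P_A = 760,
                                    Pv_L = saturation_vapor_pressure(T_L),
                                    Pv_C = RH_C * saturation_vapor_pressure(T_C),
                                    RH_C = 0.5) {
  stopifnot(length(T_L) == 1, length(T_C) == 1, length(P_A) == 1)
  if (T_L <= 0 || T_C <= 0) stop("Temperatures must be positive.", call. = FALSE)
  if (Pv_L < 0 || Pv_C < 0 || P_A <= Pv_L || P_A <= Pv_C) {
    stop("Vapor pressures must satisfy 0 <= Pv < P_A.", call. = FALSE)
  }
  out <- tibble::tibble(
    P_A = P_A, Pv_L = Pv_L, Pv_C = Pv_C, T_L = T_L, T_C = T_C,
    F_adj = volume_adjustment_factor(P_A, Pv_L, Pv_C, T_L, T_C)
  )
  class(out) <- c("conditioning_adjustment", class(out))
  out
}

#' Drorbaugh-Fenn volume adjustment factor
#'
#' Computes the dimensionless factor that scales the raw conditioning-driven
#' volume signal of a plethysmograph up to an estimated tidal volume:
#' \deqn{F_{adj} = \frac{1}{1 - \frac{P_A - Pv_L}{P_A - Pv_C}\cdot\frac{T_C}{T_L}}}
#' The factor diverges as the lung and chamber gas states approach each
#' other: with no temperature/humidity difference there is no conditioning
#' signal to amplify, and the computation is refused.
#'
#' @inheritParams conditioning_adjustment
#' @param tol Singularity guard: an error is raised when the denominator
#'   `1 - ((P_A - Pv_L)/(P_A - Pv_C)) * T_C/T_L` is smaller than `tol` in
#'   absolute value.
#' @return The adjustment factor (dimensionless). Vectorised over all
#'   arguments.
#' @export
#' @examples
#' volume_adjustment_factor(760, saturation_vapor_pressure(313.15), 0,
#'                          T_L = 313.15, T_C = 299.15)
volume_adjustment_factor <- function(P_A, Pv_L, Pv_C, T_L, T_C, tol = 1e-6) {
  if (any(T_L <= 0) || any(T_C <= 0)) {
    stop("Temperatures must be positive.", call. = FALSE)
  }
  if (any(Pv_L < 0) || any(Pv_C < 0) || any(P_A <= Pv_L) || any(P_A <= Pv_C)) {
    stop("Vapor pressures must satisfy 0 <= Pv < P_A.", call. = FALSE)
  }
  denom <- 1 - ((P_A - Pv_L) / (P_A - Pv_C)) * (T_C / T_L)
  if (any(abs(denom) < tol)) {
    stop("Lung and chamber gas states are (near-)identical: ",
         "the adjustment factor is singular.", call. = FALSE)
  }
  1 / denom
}

#' Construct a parcel of moist air
#'
#' A gas parcel is the simulator's bookkeeping unit: an amount of dry air and
#' water vapor at a temperature, occupying a volume. Parcels can be built
#' either from amounts directly or from a (pressure, temperature, volume,
#' relative humidity) state via [parcel_from_state()].
#'
#' @param n_dry Amount of dry air \[mol\], `>= 0`.
#' @param n_water Amount of water vapor \[mol\], `>= 0`. Clipped to the
#'   saturation amount at `T` (the condensed excess is recorded in the
#'   `condensed` column).
#' @param T Temperature \[K\].
#' @param V Occupied volume \[mL\], `> 0`.
#' @return A one-row tibble of class `gas_parcel` with columns `n_dry`,
#'   `n_water`, `T`, `V`, `condensed`.
#' @export
gas_parcel <- function(n_dry, n_water, T, V) {
  stopifnot(length(n_dry) == 1, length(n_water) == 1, length(T) == 1,
            length(V) == 1)
  if (V <= 0) stop("Parcel volume must be positive.", call. = FALSE)
  if (n_dry < 0 || n_water < 0) {
    stop("Amounts of gas must be non-negative.", call. = FALSE)
  }
  if (T <= 0) stop("Temperature must be positive.", call. = FALSE)
  n_sat <- saturation_vapor_pressure(T) * V / (gas_constant()$R_gas * T)
  condensed <- max(0, n_water - n_sat)
  out <- tibble::tibble(
    n_dry = n_dry, n_water = min(n_water, n_sat), T = T, V = V,
    condensed = condensed
  )
  class(out) <- c("gas_parcel", class(out))
  out
}

#' @describeIn gas_parcel Build a parcel from total pressure \[mmHg\],
#'   temperature \[K\], volume \[mL\] and relative humidity (fraction).
#' @param P Total pressure \[mmHg\].
#' @param RH Relative humidity (fraction of saturation) used to split `P`
#'   into dry and vapor partial pressures.
#' @export
parcel_from_state <- function(P, T, V, RH = 0) {
  stopifnot(RH >= 0, RH <= 1)
  Pv <- RH * saturation_vapor_pressure(T)
  if (Pv >= P) stop("Vapor partial pressure exceeds total pressure.", call. = FALSE)
  R_gas <- gas_constant()$R_gas
  gas_parcel(n_dry = (P - Pv) * V / (R_gas * T),
             n_water = Pv * V / (R_gas * T), T = T, V = V)
}

#' Total pressure of a gas parcel
#'
#' Ideal-gas pressure of the parcel's contents in its volume.
#'
#' @param parcel A `gas_parcel` (one-row tibble from [gas_parcel()]).
#' @return Pressure in mmHg.
#' @export
parcel_pressure <- function(parcel) {
  if (any(parcel$V <= 0)) stop("Parcel volume must be positive.", call. = FALSE)
  (parcel$n_dry + parcel$n_water) * gas_constant()$R_gas * parcel$T / parcel$V
}
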