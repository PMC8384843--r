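---
title: "A mechanistic model of whole-body plethysmography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of whole-body plethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plethysim)
```

## The measurement problem

Unrestrained whole-body plethysmography (WBP) infers the breathing of a
small animal from pressure changes in a chamber that encloses it. Two
distinct physical processes drive those pressure changes:

1. **Conditioning** — inspired air is warmed to body temperature and
   humidified to saturation, so it occupies more volume inside the animal
   than it did in the chamber; expired air cools back and the volume
   excess collapses. In the sealed ("barometric", PWBP) configuration
   this is the main signal.
2. **Resistance-driven compression** — when airway resistance retards the
   flow into an expanding lung, chamber gas is compressed before the
   moles can follow; the mirror effect appears during a squeeze.

In the bias-flow ("pneumotach", FWBP) configuration the chamber wall
carries a resistive leak, the pressure across it is read as a flow, and
the flow is integrated into an apparent tidal volume. The raw
conditioning-driven volume is scaled to an estimated tidal volume with
the Drorbaugh–Fenn factor,

$$F_{adj} = \frac{1}{1 - \dfrac{P_A - Pv_L}{P_A - Pv_C}\cdot\dfrac{T_C}{T_L}},$$

where $P_A$ is atmospheric pressure, $Pv_L, Pv_C$ are the water vapor
pressures in lung and chamber and $T_L, T_C$ the corresponding
temperatures (all pressures in mmHg, temperatures in K).

`plethysim` rebuilds this measurement chain around a mechanical lung
stand-in: a heated, humidified bulb of ~1.7 mL capacity whose gas volume
is squeezed between 1.41 and 1.7 mL by a servo lever, breathing through
interchangeable cannula resistances into a 1180 mL chamber. Because
every quantity in the simulator is known exactly, the errors of the
plethysmographic estimates can be measured rather than argued about.

## The simulator

### State and transport

The stepper (compiled code, `src/stepper.cpp`) tracks moles of dry air
and of water vapor plus a gas temperature for two compartments, bulb and
chamber cavity; pressures follow the ideal gas law. The bulb volume is
*prescribed*: the servo trajectory is a piecewise-linear ramp
(inspiration, default 50 ms), an optional hold, a deflation ramp
(expiration, 100 or 800 ms) and a rest, repeating at 0.5 cycles per
second. Prescribing the displacement makes the expiratory *force* an
explicit input — which is the point: the device has no elastic recoil,
so expiration is always an active act of the lever.

Transport terms, per sub-step:

* **Airway flow** follows the laminar law $Q = \Delta P / R_{aw}$. The
  open adapter has $R_{aw} = 10^{-4}$, the 20G and 27G cannulas
  effective values of 5 and 20 mmHg·s·mL⁻¹. These are calibrated
  effective values, not Poiseuille numbers: at the ~6 mL s⁻¹ inspiratory
  flows the narrow tips are far outside the laminar regime, and what
  matters for the phenomenology is the filling time constant
  $R_{aw} C_{bulb}$ (≈11 and ≈44 ms) against the 50 ms inspiration.
  The pressure-difference update is integrated *exactly* (exponential
  update) inside each sub-step, because $R_{aw} C_{bulb}$ for the open
  adapter is of order 10⁻⁷ s — hopelessly stiff for an explicit step.
* **Bulb conditioning**: the bulb gas relaxes toward the heater
  temperature (40 °C) and, while heated, its vapor content toward
  saturation, both with time constant 25 ms. These defaults are set by
  the device's reported pressure-timing (≈100 ms to build up the
  inspiratory pressure, a peak lasting ≈164 ms at the short expiration);
  slower constants smear the build-up far beyond those timings.
  Supersaturation (e.g. when cool air mixes into saturated warm gas) is
  clipped and logged as condensate.
* **Jet entrainment** (`entrain_ratio`, default 3): while the bulb
  expands, the inspiratory jet exchanges an extra
  `entrain_ratio · dV/dt` of chamber air through the heated bulb. This
  is the model's expression of dead-space and residual-volume
  recruitment: the device conditions substantially more air per cycle
  than the tidal aliquot alone, which is what makes the adjusted tidal
  volume *over*-estimate the true inspired volume. With
  `entrain_ratio = 0` the model is strictly tidal and the apparent
  volume collapses to a fraction of the truth.
* **Chamber-side cooling**: warm expelled gas relaxes toward the wall
  temperature. The relaxation rate is
  $1/\tau_{relax} + g\,\max(-dV/dt, 0)$ filtered through a turbulence
  state with 0.1 s persistence: a passively drifting plume in a 1.2 L
  chamber cools slowly ($\tau_{relax}$ = 2 s), but the expiratory jet
  stirs the chamber in proportion to the squeeze speed
  ($g$ = 20 mL⁻¹) and its turbulence outlives the squeeze briefly. A
  fast, forced expiration therefore dumps the accumulated warm excess as
  a sharp negative pressure deflection just after the squeeze, while a
  slow expiration produces none — the heart of the enhanced-pause
  analysis below. Mixing is asymmetric by design: each jet stirs the
  compartment it discharges *into* (inhalation is a gentle sink on the
  chamber side).
* **Wall coupling**: the vapor carried by the plume condenses toward the
  ambient humidity at the same mixing-limited rate (the walls hold the
  chamber near its hygrometer reading), and the heat shed by the gas
  warms the walls, whose heat capacity is 300× that of the chamber gas.
  The latter is what makes the sealed chamber's baseline ratchet upward
  cycle after cycle under continuous heating, until the calibration
  valve vents it.
* **Leak and bias flow** (flow mode): the leak resistance is derived
  from the requested time constant via the isothermal compliance
  $C = V_{gas}/P_{atm}$, so the chamber decays with exactly
  $\tau = R C$ and filters as a sensor with corner frequency
  $f_c = 1/(2\pi\tau)$. A 150 mL min⁻¹ bias flow is withdrawn
  continuously.

Dry-air moles are conserved by construction: bulb + chamber + everything
exported through leak, bias and calibration events stays constant to
floating-point accumulation (~10⁻¹²), and `conservation_error()` exposes
the ledger.

### Numerics

The scheme is first-order operator splitting at 40 sub-steps per output
sample (1 kHz), chosen so that halving the sub-step changes no output
sample by more than ≈0.05% of the trace peak. All simulations here use
8 cycles of 2 s with the first 3 discarded as start-up transient — small
enough that the full experimental matrix runs in seconds, long enough
that the periodic state is reached to well below the measurement scale.
The core simulator is deterministic; optional Gaussian sensor noise uses
an explicitly recorded seed.

## The analysis chain

The recorded differential pressure is processed the way the acquisition
software does it:

1. **Two-point flow calibration** against the bias flow
   (`calibrate_flow_from_bias()`): bias off ↔ 0, bias on ↔ −150 mL min⁻¹.
2. **Zero-phase band-pass** 0.5–20 Hz (2nd-order Butterworth, run
   forward and backward). The family and order are the package's choice;
   only the band is inherited from practice. Zero phase preserves the
   cross-channel timing comparisons.
3. **Integration with cycle reset** (`integrate_with_reset()`):
   trapezoidal, reset to zero at every sample where the flow crosses
   from non-positive to positive — the documented integral semantics of
   the acquisition software, with no sub-sample interpolation.
4. **Breath segmentation**: reset-to-reset windows
   (`segment_breaths()`), or — when the servo protocol is known, as it
   is for every simulated recording — one window per cycle
   (`protocol_breaths()`). The protocol windows are the recommended
   route: the conditioning rebound after a resisted expiration re-crosses
   zero mid-cycle, and reset-based windows would split such cycles in
   two. Tidal volume is the within-window volume peak (earliest sample
   on ties); the rate comes from the window starts.
5. **Adjustment**: `adjV_T = F_adj · V_T`, with $T_L$ taken from the
   heater set point, $T_C$ and the chamber humidity (default 50% RH)
   from the chamber configuration. The saturation vapor pressure is a
   Magnus-form closed formula (Arden Buck coefficients), accurate to a
   few tenths of a percent over the working range. Note the factor is
   *singular* when lung and chamber gas states coincide — no
   conditioning, nothing to amplify — and the package refuses to
   compute it there.

In the sealed mode the pressure axis is calibrated instead by a syringe
step (`closed_chamber_volume_calibration()`): 500 µL injected, the step
read as the difference of 200 ms pre/post medians with a 50 ms guard.
The chamber time constant itself is estimated from occlusion-release
decays by log-linear least squares between 90% and 10% of the peak
(`estimate_tau()`), bounds chosen to dodge the release transient and the
noise floor; both window sets are configurable.

## The enhanced pause

Per breath, with the volume peak as the inspiration/expiration divide:
PIF and PEF are the peak phase flows, Te runs from the volume peak to
the beginning of the next inspiration, Rt is the time for the volume to
fall by 65% of its peak-to-end-expiratory excursion (linearly
interpolated), and

$$Penh = \left(\frac{T_e}{R_t} - 1\right)\cdot\frac{PEF}{PIF}.$$

The combining formula is the canonical one the parameter's users
presuppose; it is dimensionless and invariant under rescaling of the
signals and of time (property-tested). Both the per-breath table and
mean/median summaries are reported, since averaged traces can be
summarised either way.

The simulator reproduces the parameter's known pathology: Penh rises
with the cannula resistance at the fast expiration, yet collapses by
more than an order of magnitude when only the expiration is slowed —
with the resistance untouched — because PEF and the sharpness of the
volume drop are set by the lever speed (the expiratory force), not by
the resistance. The model makes the mechanism explicit: the sharp
expiratory deflection is the jet-mixed cool-down of accumulated warm
gas plus the resistance-driven compression, both proportional to the
squeeze speed.

## What the generator emulates, and what it does not

The defaults are the study conditions of the emulated bench device:
1 kHz sampling, 50 ms inspiration, 100/800 ms expiration at 0.5 s⁻¹,
1180 mL chamber with a 58 ms default leak constant (tunable over the
40–378 ms tube-length series), 150 mL min⁻¹ bias flow, heater at 40 °C
against a 26 °C chamber, and ~0.29 mL of tidal excursion. Free
parameters that no bench measurement pins down — the conditioning time
constants, the entrainment ratio, the jet-mixing gain and persistence,
the chamber humidity, the wall heat capacity — were set once from the
device's reported timings and readout scales plus physical reasoning,
and are all exposed in `alm_config()` / `chamber_config()`.

Passing tests on this generator therefore show that the *pipeline* is
correct and that the *mechanisms* suffice to produce the observed
phenomenology; they do not show that a live animal behaves like a
servo-squeezed bulb. Known idealisations: perfect mixing within each
compartment (no stratification; the real bulb is bottom-heated),
a linear airway law (turbulence folded into effective resistances),
isothermal compliances, an ideal reference chamber, no elastic recoil,
no gas exchange (the model neither consumes oxygen nor produces CO₂),
and a conditioning response that saturates as the entrained volume
approaches the bulb capacity — so the chamber signal is linear in the
tidal excursion only for the mechanical component, not for the heated
one.

## A worked run

```{r, eval = FALSE}
library(plethysim)

sim <- simulate_condition("none", heater_on = TRUE, t_exp = 0.1,
                          tau = 0.058, n_cycles = 8)
an <- analyze_breathing(sim)
glance(an)
#> # A tibble: 1 x 5
#>   n_breaths   f_r v_t_ul adj_v_t_ul f_adj
#>       <int> <dbl>  <dbl>      <dbl> <dbl>
#> 1         5    30   39.0       392.  10.1
device_tidal_volume(sim)
#> [1] 278.3418
```

The apparent (adjusted) tidal volume overestimates the true inspired
volume, and re-running with `t_exp = 0.8` overestimates it further —
the central finding the simulator exists to dissect. `run_scenario()`
bundles the full experimental matrices (`list_scenarios()`), and
`autoplot()` on any simulation shows all recorded channels.

## Degenerate inputs and tie-breaks

* Equal-height volume peaks inside a window: the earliest sample wins.
* `align_and_subtract()` picks the cross-correlation-optimal lag within
  ±10 samples, but lags within 0.02 correlation of the optimum count as
  ties and the smallest magnitude wins — cycle-locked pairs must not be
  nudged off zero by the slow asymmetric conditioning component.
* A trace that never decays through the 90–10% band, a step below the
  noise floor, a flow-free cycle, or a volume that never sheds 65% of
  its excursion each raise a specific error rather than a number.
* The adjustment factor raises an error within a configurable tolerance
  of its singularity.
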