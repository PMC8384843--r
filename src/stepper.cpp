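#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Operator-split fixed-substep integrator for the artificial-lung /
// plethysmography-chamber gas system. Moles of dry air and water vapor and
// the gas temperature are tracked per compartment; pressures follow the
// ideal gas law. The bulb volume is prescribed (stiff displacement model).
//
// Pressure-driven exchanges (airway, chamber leak) are advanced with an
// exact exponential update of the pressure difference within each substep:
// the airway equilibration time constant R_aw*C_bulb can be orders of
// magnitude below the substep for the open adapter, which would make an
// explicit update unstable.

static inline double svp_mmHg(double TK) {
  double t = TK - 273.15;
  return 6.1121 * exp((18.678 - t / 234.5) * t / (257.14 + t)) * 0.75006168;
}

// [[Rcpp::export]]
List simulate_wbp_cpp(NumericVector v_target, double dt, int n_sub,
                      double r_aw, double tau_thermal, double tau_humid,
                      double t_heater, bool heater_on,
                      double t_bulb0, double rh_bulb0,
                      double v_chamber, double r_leak, double bias_q,
                      double t_wall, double p_atm, double rh_chamber,
                      double tau_chamber_relax, double p0_offset,
                      IntegerVector event_idx, NumericVector event_vol,
                      IntegerVector reset_idx, bool bulb_displaces,
                      double entrain_ratio, double mixing_gain,
                      double tau_turb, double wall_capacity) {
  const double R_gas = 62363.67;
  const int N = v_target.size();
  const int n_out = N / n_sub;

  // --- initial state ------------------------------------------------------
  double V_b = v_target[0];
  double T_b = t_bulb0;
  double pw_b = rh_bulb0 * svp_mmHg(T_b);
  double n_w_b = pw_b * V_b / (R_gas * T_b);
  double n_d_b = (p_atm - pw_b) * V_b / (R_gas * T_b);

  // when the bulb sits outside the chamber (device-calibration rig) its
  // displacement does not compress the chamber gas
  double V_cav = v_chamber - (bulb_displaces ? V_b : 0.0);
  double T_c = t_wall;
  double pw_c = rh_chamber * svp_mmHg(t_wall);
  double P_c0 = p_atm + p0_offset;
  double n_w_c = pw_c * V_cav / (R_gas * T_c);
  double n_d_c = (P_c0 - pw_c) * V_cav / (R_gas * T_c);

  const double dry_total0 = n_d_b + n_d_c;
  double dry_exported = 0.0;   // net dry moles that left through leak/bias/valve
  double condensed = 0.0;      // water condensed out on supersaturation clips
  double water_added = 0.0;    // water evaporated into the bulb by the humidifier

  const double a_th  = 1.0 - exp(-dt / tau_thermal);
  const double a_hum = 1.0 - exp(-dt / tau_humid);
  const double a_turb = 1.0 - exp(-dt / tau_turb);
  double turb = 0.0;           // jet-induced chamber mixing intensity [1/s]
  double t_wall_dyn = t_wall;  // wall temperature; warms as it absorbs heat
  const bool leaky = R_FINITE(r_leak) && r_leak > 0;
  const bool exchange = R_FINITE(r_aw);

  NumericMatrix out(n_out, 7); // dps, p_bulb, t_bulb, q_aw, v_bulb, q_leak, t_chamber

  // sample 0 is the initial state, sample j the state at time j*n_sub*dt
  {
    double P_b0 = (n_d_b + n_w_b) * R_gas * T_b / V_b;
    double P_cc = (n_d_c + n_w_c) * R_gas * T_c / V_cav;
    out(0, 0) = P_cc - p_atm;
    out(0, 1) = P_b0 - p_atm;
    out(0, 2) = T_b;
    out(0, 3) = 0.0;
    out(0, 4) = V_b;
    out(0, 5) = 0.0;
    out(0, 6) = T_c;
  }

  int ev = 0, rv = 0;
  const int n_ev = event_idx.size(), n_rv = reset_idx.size();

  for (int i = 0; i < N; ++i) {
    V_b = v_target[i];
    V_cav = v_chamber - (bulb_displaces ? V_b : 0.0);

    // bulb conditioning: warming toward the heater (or the wall when off),
    // humidification toward saturation while the heater is on
    double T_target = heater_on ? t_heater : t_wall;
    T_b += (T_target - T_b) * a_th;
    double n_sat_b = svp_mmHg(T_b) * V_b / (R_gas * T_b);
    if (heater_on) {
      double dn_w = (n_sat_b - n_w_b) * a_hum;
      if (dn_w > 0) { n_w_b += dn_w; water_added += dn_w; }
    }
    if (n_w_b > n_sat_b) { condensed += n_w_b - n_sat_b; n_w_b = n_sat_b; }

    // airway exchange (exponential update of the pressure difference)
    double n_b = n_d_b + n_w_b, n_c = n_d_c + n_w_c;
    double P_b = n_b * R_gas * T_b / V_b;
    double P_c = n_c * R_gas * T_c / V_cav;
    double q_aw = 0.0;
    if (exchange) {
      double dP = P_c - P_b;
      if (dP != 0.0) {
        bool from_chamber = dP > 0;
        double T_src = from_chamber ? T_c : T_b;
        double P_src = from_chamber ? P_c : P_b;
        double vm = R_gas * T_src / P_src;           // molar volume at source
        double K = R_gas * T_c / V_cav + R_gas * T_b / V_b;
        double tau_ex = r_aw * vm / K;
        double f = 1.0 - exp(-dt / tau_ex);
        double dn = (dP / K) * f;                    // moles chamber -> bulb
        q_aw = dn * vm / dt;
        if (from_chamber) {
          double xw = n_w_c / n_c;
          double dnw = dn * xw, dnd = dn - dnw;
          n_w_c -= dnw; n_d_c -= dnd;
          T_b = (n_b * T_b + dn * T_c) / (n_b + dn);
          n_w_b += dnw; n_d_b += dnd;
        } else {
          double xw = n_w_b / n_b;
          double dnw = dn * xw, dnd = dn - dnw;      // dn < 0: leaves bulb
          n_w_b += dnw; n_d_b += dnd;
          T_c = (n_c * T_c - dn * T_b) / (n_c - dn);
          n_w_c -= dnw; n_d_c -= dnd;
        }
      }
    }

    // jet entrainment: the inspiratory jet entrains extra chamber air
    // through the heated bulb in proportion to its own speed, so more gas
    // than the tidal aliquot is conditioned each cycle (dead-space and
    // residual-volume recruitment)
    double dvdt = (i > 0) ? (v_target[i] - v_target[i - 1]) / dt : 0.0;
    if (exchange && entrain_ratio > 0 && dvdt > 0) {
      n_b = n_d_b + n_w_b; n_c = n_d_c + n_w_c;
      double P_now = n_c * R_gas * T_c / V_cav;
      double vm = R_gas * T_c / P_now;
      double dn_ex = entrain_ratio * dvdt * dt / vm;
      double xw_c = n_w_c / n_c, xw_b = n_w_b / n_b;
      // chamber air into the bulb
      T_b = (n_b * T_b + dn_ex * T_c) / (n_b + dn_ex);
      n_w_b += dn_ex * xw_c; n_d_b += dn_ex * (1.0 - xw_c);
      n_w_c -= dn_ex * xw_c; n_d_c -= dn_ex * (1.0 - xw_c);
      // bulb air into the chamber
      n_b = n_d_b + n_w_b; n_c = n_d_c + n_w_c;
      T_c = (n_c * T_c + dn_ex * T_b) / (n_c + dn_ex);
      n_w_c += dn_ex * xw_b; n_d_c += dn_ex * (1.0 - xw_b);
      n_w_b -= dn_ex * xw_b; n_d_b -= dn_ex * (1.0 - xw_b);
    }

    // chamber gas relaxes to the wall temperature. Each jet mixes the
    // compartment it discharges into: the expiratory jet stirs the
    // chamber in proportion to the squeeze speed, and its turbulence
    // persists briefly after the squeeze, so a fast, forced expiration
    // dumps the accumulated warm excess as a sharp negative pressure
    // deflection just after the squeeze; a slow squeeze does not. During
    // inspiration the chamber-side inlet flow is a gentle sink and the
    // warm excess is left in place.
    double s_int = (dvdt < 0) ? mixing_gain * (-dvdt) : 0.0;
    turb += (s_int - turb) * a_turb;
    double mix_rate = 1.0 / tau_chamber_relax + turb;
    double a_now = 1.0 - exp(-dt * mix_rate);
    // heat leaving the gas warms the walls (finite wall heat capacity,
    // expressed as a multiple of the chamber gas heat capacity); in a
    // closed chamber this slowly ratchets the baseline pressure upward
    double dT_gas = (t_wall_dyn - T_c) * a_now;
    T_c += dT_gas;
    t_wall_dyn -= dT_gas / wall_capacity;
    // the saturated warm plume condenses its vapor excess as it cools;
    // the chamber walls hold the gas near the ambient humidity, at the
    // same mixing-limited transport rate
    double n_w_amb = rh_chamber * svp_mmHg(T_c) * V_cav / (R_gas * T_c);
    double dw = (n_w_c - n_w_amb) * a_now;
    n_w_c -= dw; condensed += dw;
    double n_sat_c = svp_mmHg(T_c) * V_cav / (R_gas * T_c);
    if (n_w_c > n_sat_c) { condensed += n_w_c - n_sat_c; n_w_c = n_sat_c; }

    // leak through the chamber inlet (pneumotach) and bias flow
    n_c = n_d_c + n_w_c;
    P_c = n_c * R_gas * T_c / V_cav;
    double q_leak = 0.0;
    if (leaky) {
      double P_rel = P_c - p_atm;
      if (P_rel != 0.0) {
        bool outflow = P_rel > 0;
        double T_src = outflow ? T_c : t_wall;
        double P_src = outflow ? P_c : p_atm;
        double vm = R_gas * T_src / P_src;
        double K_l = R_gas * T_c / V_cav;
        double tau_l = r_leak * vm / K_l;
        double f = 1.0 - exp(-dt / tau_l);
        double dn_l = (P_rel / K_l) * f;             // moles chamber -> outside
        q_leak = dn_l * vm / dt;
        if (outflow) {
          double xw = n_w_c / n_c;
          n_w_c -= dn_l * xw;
          double dnd = dn_l * (1.0 - xw);
          n_d_c -= dnd; dry_exported += dnd;
        } else {
          double din = -dn_l;
          double pw_a = rh_chamber * svp_mmHg(t_wall);
          double xw_a = pw_a / p_atm;
          T_c = (n_c * T_c + din * t_wall) / (n_c + din);
          n_w_c += din * xw_a;
          double dnd = din * (1.0 - xw_a);
          n_d_c += dnd; dry_exported -= dnd;
        }
        n_c = n_d_c + n_w_c;
        P_c = n_c * R_gas * T_c / V_cav;
      }
      if (bias_q > 0) {
        double vm_c = R_gas * T_c / P_c;
        double dnb = bias_q * dt / vm_c;
        double xw = n_w_c / n_c;
        n_w_c -= dnb * xw;
        double dnd = dnb * (1.0 - xw);
        n_d_c -= dnd; dry_exported += dnd;
      }
    }

    // calibration events: syringe injection/withdrawal, baseline-reset valve
    if (ev < n_ev && event_idx[ev] == i) {
      double vol = event_vol[ev]; ++ev;
      if (vol > 0) { // inject ambient air
        double dn = p_atm * vol / (R_gas * t_wall);
        double pw_a = rh_chamber * svp_mmHg(t_wall);
        double xw_a = pw_a / p_atm;
        n_c = n_d_c + n_w_c;
        T_c = (n_c * T_c + dn * t_wall) / (n_c + dn);
        n_w_c += dn * xw_a;
        double dnd = dn * (1.0 - xw_a);
        n_d_c += dnd; dry_exported -= dnd;
      } else {       // withdraw chamber gas
        n_c = n_d_c + n_w_c;
        double P_now = n_c * R_gas * T_c / V_cav;
        double dn = P_now * (-vol) / (R_gas * T_c);
        double xw = n_w_c / n_c;
        n_w_c -= dn * xw;
        double dnd = dn * (1.0 - xw);
        n_d_c -= dnd; dry_exported += dnd;
      }
    }
    if (rv < n_rv && reset_idx[rv] == i) {
      ++rv; // vent the chamber to ambient pressure
      n_c = n_d_c + n_w_c;
      double P_now = n_c * R_gas * T_c / V_cav;
      double fac = p_atm / P_now;
      dry_exported += n_d_c * (1.0 - fac);
      n_d_c *= fac; n_w_c *= fac;
    }

    if ((i + 1) % n_sub == 0 && (i + 1) / n_sub < n_out) {
      int j = (i + 1) / n_sub;
      n_b = n_d_b + n_w_b; n_c = n_d_c + n_w_c;
      double P_b_now = n_b * R_gas * T_b / V_b;
      double P_c_now = n_c * R_gas * T_c / V_cav;
      out(j, 0) = P_c_now - p_atm;
      out(j, 1) = P_b_now - p_atm;
      out(j, 2) = T_b;
      out(j, 3) = q_aw;
      out(j, 4) = V_b;
      out(j, 5) = q_leak;
      out(j, 6) = T_c;
    }
  }

  return List::create(
    _["traces"] = out,
    _["dry_total0"] = dry_total0,
    _["dry_bulb"] = n_d_b,
    _["dry_chamber"] = n_d_c,
    _["dry_exported"] = dry_exported,
    _["condensed"] = condensed,
    _["water_added"] = water_added);
}
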