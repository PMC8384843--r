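# small synthetic traces used across the suite

make_trace <- function(x, fs = 1000, name = "value") {
  out <- tibble::tibble(time = (seq_along(x) - 1) / fs, value = x)
  names(out)[2] <- name
  out
}

decay_trace <- function(tau, fs = 1000, duration = 6 * tau, noise_sd = 0) {
  t <- seq(0, duration, by = 1 / fs)
  make_trace(exp(-t / tau) + stats::rnorm(length(t), sd = noise_sd), fs, "p")
}

step_trace <- function(step_at = 0.5, amplitude = 1, duration = 1, fs = 1000,
                       noise_sd = 0) {
  t <- seq(0, duration, by = 1 / fs)
  make_trace(ifelse(t < step_at, 0, amplitude) +
               stats::rnorm(length(t), sd = noise_sd), fs, "p")
}

# a short default simulation shared by several tests
quick_sim <- function(resistance = "none", heater_on = TRUE, t_exp = 0.1,
                      mode = "flow", n_cycles = 6, ...) {
  simulate_condition(resistance, heater_on = heater_on, t_exp = t_exp,
                     mode = mode, n_cycles = n_cycles, ...)
}

# build a two-window breath table around hand-crafted flow/volume traces
penh_fixture <- function(flow, volume, i_peak, onset, fs = 1000) {
  n <- length(flow)
  v_peak <- volume[i_peak]
  br <- tibble::tibble(
    cycle = 1:2,
    t_start = c(0, (onset - 1) / fs), t_end = c((onset - 2) / fs, (n - 1) / fs),
    t_peak = c((i_peak - 1) / fs, NA),
    i_start = c(1L, as.integer(onset)), i_end = c(as.integer(onset - 1), n),
    i_peak = c(as.integer(i_peak), as.integer(onset)),
    v_t = c(v_peak, 0), f_r = NA_real_)
  compute_penh(make_trace(flow, fs, "flow"), make_trace(volume, fs, "volume"),
               breaths = br)
}
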