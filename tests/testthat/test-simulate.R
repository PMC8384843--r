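test_that("chamber pressure decays with the configured time constant", {
  ch <- chamber_config(mode = "flow", tau = 0.058, bias_flow = 0)
  sim <- run_simulation(alm_config(heater_on = FALSE),
                        servo_protocol(cycle_period = 1.5, n_cycles = 1),
                        ch, static_bulb = TRUE, p0_offset = 1)
  fit <- estimate_tau(tibble::tibble(time = sim$time, p = sim$dps))
  expect_equal(fit$tau, 0.058, tolerance = 0.01)
})

test_that("a sealed heated bulb relaxes with tau_thermal", {
  alm <- alm_config(resistance = Inf)
  alm$r_aw <- Inf # sealed: no airway flux at all
  sim <- run_simulation(alm, servo_protocol(cycle_period = 1, n_cycles = 1),
                        chamber_config(mode = "closed"), static_bulb = TRUE,
                        t_bulb0 = 299.15, rh_bulb0 = 0.5)
  fit <- estimate_tau(tibble::tibble(time = sim$time,
                                     x = alm$t_heater - sim$t_bulb))
  expect_equal(fit$tau, alm$tau_thermal, tolerance = 0.01)
})

test_that("an unheated system in equilibrium stays put", {
  sim <- run_simulation(alm_config(heater_on = FALSE),
                        servo_protocol(cycle_period = 1, n_cycles = 1),
                        chamber_config(mode = "closed"), static_bulb = TRUE)
  expect_lt(max(abs(sim$dps)), 1e-9)
  expect_lt(diff(range(sim$t_bulb)), 1e-9)
})

test_that("dry air is conserved to 1e-9 in both recording modes", {
  flow <- quick_sim("20G", TRUE, n_cycles = 10)
  closed <- quick_sim("20G", TRUE, mode = "closed", n_cycles = 10)
  expect_lt(conservation_error(flow), 1e-9)
  expect_lt(conservation_error(closed), 1e-9)
})

test_that("an injected half millilitre raises closed-chamber pressure per Boyle", {
  ch <- chamber_config(mode = "closed")
  alm <- alm_config(heater_on = FALSE)
  sim <- run_simulation(alm, servo_protocol(cycle_period = 2, n_cycles = 1),
                        ch, static_bulb = TRUE,
                        inject_times = 1, inject_volumes = 0.5)
  expected <- ch$p_atm * 0.5 / (ch$v_chamber - alm$v_min)
  expect_equal(sim$dps[nrow(sim)], expected, tolerance = 0.01)
})

test_that("halving the substep changes no sample by more than 0.1% of peak", {
  a <- quick_sim("20G", TRUE, n_cycles = 3)                 # n_sub = 40
  b <- quick_sim("20G", TRUE, n_cycles = 3, n_sub = 80)
  expect_lt(max(abs(a$dps - b$dps)) / max(abs(a$dps)), 1e-3)
})

test_that("closed-mode heating ratchets the baseline up until the valve resets it", {
  sim <- quick_sim("none", TRUE, mode = "closed", n_cycles = 10)
  baselines <- vapply(4:9, function(k) sim$dps[k * 2000 + 1], numeric(1))
  expect_true(all(diff(baselines) > 0))
  with_reset <- run_simulation(alm_config(), servo_protocol(n_cycles = 6),
                               chamber_config(mode = "closed"),
                               reset_times = 9.999)
  expect_lt(abs(with_reset$dps[10001]), 0.002 * max(abs(with_reset$dps)))
})

test_that("steady-state leak plus bias flux balances the bias flow", {
  sim <- quick_sim("none", TRUE, n_cycles = 8)
  late <- sim$time >= 6
  bias <- attr(sim, "chamber")$bias_flow / 60
  expect_equal(mean(sim$q_leak[late]), -bias, tolerance = 0.02)
})

test_that("the mechanical chamber signal is linear in the tidal excursion", {
  pk <- function(v_min) {
    alm <- alm_config(v_min = v_min, resistance = "20G", heater_on = FALSE)
    sim <- run_simulation(alm, servo_protocol(n_cycles = 6),
                          chamber_config(tau = 0.058))
    avg <- cycle_average(tibble::tibble(time = sim$time, dps = sim$dps),
                         servo_protocol(n_cycles = 6), discard = 3)
    max(abs(avg$dps - stats::median(avg$dps)))
  }
  expect_equal(pk(1.41) / pk(1.555), 2, tolerance = 0.05)
})

test_that("conditioning humidifies only while heated, and stays quiet unheated", {
  hot <- quick_sim("none", TRUE, n_cycles = 4)
  expect_gt(attr(hot, "conservation")$water_added, 0)
  cold <- quick_sim("none", FALSE, n_cycles = 4)
  expect_lt(diff(range(cold$t_bulb[cold$time >= 2])), 0.01)
})

test_that("measurement noise is reproducible from the recorded seed", {
  a <- run_simulation(alm_config(), servo_protocol(n_cycles = 1),
                      chamber_config(), noise_sd = 0.01, seed = 7L)
  b <- run_simulation(alm_config(), servo_protocol(n_cycles = 1),
                      chamber_config(), noise_sd = 0.01, seed = 7L)
  c <- run_simulation(alm_config(), servo_protocol(n_cycles = 1),
                      chamber_config(), noise_sd = 0.01, seed = 8L)
  expect_identical(a$dps, b$dps)
  expect_false(identical(a$dps, c$dps))
  expect_identical(attr(a, "seed"), 7L)
})
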