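test_that("bulb trajectory ramps, holds and repeats exactly", {
  pro <- servo_protocol(t_insp = 0.05, t_exp = 0.1, cycle_period = 2,
                        n_cycles = 3, fs = 1000)
  alm <- alm_config()
  traj <- bulb_volume_trajectory(pro, alm)
  expect_equal(traj$v_bulb[1], alm$v_min)
  # reaches v_max exactly 50 samples after the ramp start at 1 kHz
  expect_equal(traj$v_bulb[51], alm$v_max)
  expect_lt(traj$v_bulb[50], alm$v_max)
  # back at v_min after the expiratory ramp, and held there
  expect_equal(traj$v_bulb[151], alm$v_min)
  expect_true(all(traj$v_bulb[152:2000] == alm$v_min))
  # exactly periodic; net volume change over a full cycle is zero
  expect_equal(traj$v_bulb[1:2000], traj$v_bulb[2001:4000])
  expect_equal(sum(diff(traj$v_bulb[1:2001])), 0)
})

test_that("slow expiration scales the expiratory slope down by its duration", {
  alm <- alm_config()
  fast <- bulb_volume_trajectory(servo_protocol(t_exp = 0.1, n_cycles = 1),
                                 alm)
  slow <- bulb_volume_trajectory(servo_protocol(t_exp = 0.8, n_cycles = 1),
                                 alm)
  exp_slope <- function(tr) max(-diff(tr$v_bulb))
  expect_equal(exp_slope(fast) / exp_slope(slow), 8, tolerance = 1e-9)
})

test_that("airway flow follows the linear pressure-flow law", {
  expect_equal(airway_flow(760, 760, 0.1), 0)
  expect_equal(airway_flow(760, 761, 0.1), 10)
  expect_equal(airway_flow(760, 761, 0.2), 5)
  expect_equal(airway_flow(761, 760, 0.1), -10)
  expect_error(airway_flow(760, 761, 0), "positive")
})

test_that("named cannulas map to ordered effective resistances", {
  r <- vapply(c("none", "20G", "27G"), airway_resistance, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_equal(airway_resistance(0), 1e-4)   # open adapter floor
  expect_equal(airway_resistance(2.5), 2.5)
  expect_error(airway_resistance(-1))
})

test_that("protocol validation catches inconsistent timing", {
  expect_error(servo_protocol(t_insp = 1, t_exp = 1.5, cycle_period = 2),
               "cycle_period")
  expect_error(servo_protocol(fs = 50), "Sampling rate")
  expect_error(alm_config(v_max = 1, v_min = 1.2))
})
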