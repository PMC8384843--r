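test_that("a linear volume decay gives the closed-form Penh", {
  fs <- 1000
  # inspiration 0-0.2 s at +1; expiration: linear decay over Te = 1 s
  t <- seq(0, 2, by = 1 / fs)
  flow <- ifelse(t < 0.2, 1, ifelse(t < 1.2, -0.2, 0))
  volume <- cumsum(flow) / fs
  pm <- penh_fixture(flow, volume, i_peak = 201, onset = 1201)
  expect_equal(pm$te, 1, tolerance = 0.005)
  expect_equal(pm$rt, 0.65, tolerance = 0.005)
  expect_equal(pm$penh, (1 / 0.65 - 1) * (0.2 / 1), tolerance = 0.01)
})

test_that("PEF = PIF with Te = 2 Rt gives Penh of exactly one", {
  fs <- 1000
  rt <- 0.4
  # volume: peak 1 at 0.2 s, falls 65% linearly over rt, the rest over a
  # second rt; flow crafted so PIF = PEF = 1
  t <- seq(0, 1, by = 1 / fs)
  volume <- ifelse(t < 0.2, t / 0.2,
            ifelse(t < 0.2 + rt, 1 - 0.65 * (t - 0.2) / rt,
            ifelse(t < 0.2 + 2 * rt, 0.35 - 0.35 * (t - 0.6) / rt, 0)))
  flow <- ifelse(t < 0.2, 1, ifelse(t < 0.2 + 2 * rt, -1, 0))
  pm <- penh_fixture(flow, volume, i_peak = 201, onset = 201 + 2 * rt * fs)
  expect_equal(pm$te / pm$rt, 2, tolerance = 0.01)
  expect_equal(pm$penh, 1, tolerance = 0.01)
})

test_that("Penh is invariant under amplitude and time rescaling", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  flow <- ifelse(t < 0.2, sin(pi * t / 0.2),
                 ifelse(t < 0.5, -1.3 * sin(pi * (t - 0.2) / 0.3), -0.01))
  volume <- cumsum(flow) / fs
  base <- penh_fixture(flow, volume, i_peak = which.max(volume), onset = 1801)

  scaled <- penh_fixture(5 * flow, 5 * volume, i_peak = which.max(volume),
                         onset = 1801)
  expect_equal(scaled$penh, base$penh, tolerance = 1e-12)
  expect_equal(scaled$pif, 5 * base$pif)

  # stretch time by 2 (same samples, half the sampling rate)
  stretched <- penh_fixture(flow, volume, i_peak = which.max(volume),
                            onset = 1801, fs = 500)
  expect_equal(stretched$te, 2 * base$te)
  expect_equal(stretched$rt, 2 * base$rt, tolerance = 1e-9)
  expect_equal(stretched$penh, base$penh, tolerance = 1e-9)
})

test_that("a fast-then-slow expiration shortens Rt and raises Penh", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  te_end <- 1.2
  # single exponential vs two-exponential (fast then slow), same Te
  v1 <- ifelse(t < 0.2, t / 0.2, exp(-(t - 0.2) / 0.3))
  v2 <- ifelse(t < 0.2, t / 0.2,
               0.7 * exp(-(t - 0.2) / 0.05) + 0.3 * exp(-(t - 0.2) / 0.6))
  f1 <- c(0, diff(v1)) * fs
  f2 <- c(0, diff(v2)) * fs
  p1 <- penh_fixture(f1, v1, i_peak = 201, onset = te_end * fs + 201)
  p2 <- penh_fixture(f2, v2, i_peak = 201, onset = te_end * fs + 201)
  expect_lt(p2$rt, p1$rt)
  expect_gt(p2$penh, p1$penh)
})

test_that("degenerate cycles are rejected with informative errors", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  # no positive inspiratory flow
  expect_error(penh_fixture(rep(-1, length(t)), cumsum(rep(-1, length(t))) / fs,
                            i_peak = 10, onset = 900),
               "inspiratory")
  # volume never falls: flat after peak
  flow <- ifelse(t < 0.2, 1, 0)
  vol <- cumsum(flow) / fs
  expect_error(penh_fixture(flow, vol, i_peak = 600, onset = 900),
               "expiratory|65")
})

test_that("protocol windows segment a simulated recording one-per-cycle", {
  sim <- quick_sim("27G", TRUE, n_cycles = 6)
  an <- analyze_breathing(sim)
  br <- protocol_breaths(an$volume, attr(sim, "protocol"))
  expect_equal(nrow(br), 3)        # cycles 3..5 survive the 3-cycle discard
  expect_equal(br$f_r[1], 30, tolerance = 1e-6)
  pm <- penh_metrics(an)
  expect_equal(nrow(pm), nrow(br) - 1)
  expect_true(all(pm$rt <= pm$te))
  expect_true(all(pm$penh > 0))
})
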