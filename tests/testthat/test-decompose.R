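test_that("cycle averaging reproduces an exactly periodic trace", {
  fs <- 1000
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * t / 2) + 0.3 * cos(2 * pi * 3 * t)
  avg <- cycle_average(make_trace(x, fs), cycle_period = 2)
  expect_equal(avg$value, x[1:2000], tolerance = 1e-12)
  expect_equal(attr(avg, "n_cycles"), 4)
})

test_that("cycle averaging suppresses noise by about sqrt(n)", {
  set.seed(77)
  fs <- 1000
  n_cycles <- 10
  t <- seq(0, 2 * n_cycles - 1 / fs, by = 1 / fs)
  clean <- sin(2 * pi * t / 2)
  noisy <- clean + rnorm(length(t), sd = 0.5)
  avg <- cycle_average(make_trace(noisy, fs), cycle_period = 2)
  resid_sd <- stats::sd(avg$value - clean[1:2000])
  expect_equal(resid_sd, 0.5 / sqrt(n_cycles), tolerance = 0.15)
})

test_that("cycle averaging refuses insufficient data", {
  tr <- make_trace(rnorm(8000), 1000)
  expect_error(cycle_average(tr, cycle_period = 2, n_min = 5),
               "Insufficient")
})

test_that("baseline detrending re-references each epoch to its start", {
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  drifting <- sin(2 * pi * t / 2) + 0.05 * t
  avg <- cycle_average(make_trace(drifting, fs), cycle_period = 2,
                       detrend = "baseline")
  expect_equal(avg$value[1], 0)
  # the per-epoch offset is removed; the within-epoch component remains
  expect_equal(avg$value, sin(2 * pi * t[1:2000] / 2) + 0.05 * t[1:2000],
               tolerance = 1e-9)
})

test_that("subtracting identical traces gives zeros at zero lag", {
  tr <- make_trace(sin(seq(0, 20, by = 0.001)), 1000)
  d <- align_and_subtract(tr, tr)
  expect_equal(attr(d, "lag"), 0L)
  expect_true(all(d$value == 0))
})

test_that("a known additive component is recovered exactly", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  cold <- make_trace(sin(2 * pi * t / 2) + 0.4 * sin(2 * pi * 5 * t), fs)
  comp <- 0.2 * exp(-((t %% 2) - 0.3)^2 / 0.01)
  hot <- cold
  hot$value <- cold$value + comp
  d <- align_and_subtract(hot, cold)
  expect_equal(attr(d, "lag"), 0L)
  expect_equal(d$value, comp, tolerance = 1e-12)
})

test_that("a genuine shift of a sharp-featured trace is found", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  pulse <- exp(-((t %% 1) - 0.2)^2 / 2e-5) # 10 ms wide pulses
  x <- make_trace(pulse, fs)
  y <- make_trace(dplyr::lag(pulse, 5, default = 0), fs)
  d <- align_and_subtract(x, y)
  expect_equal(abs(attr(d, "lag")), 5L)
  expect_lt(max(abs(d$value)), 1e-6)
})

test_that("incompatible sampling rates are rejected", {
  a <- make_trace(rnorm(100), 1000)
  b <- make_trace(rnorm(100), 500)
  expect_error(align_and_subtract(a, b), "incompatible")
})

test_that("heated-minus-unheated isolates the conditioning component", {
  # the central decomposition claim made quantitative: with both
  # pressure components present, subtraction recovers the heat-only trace
  avg_of <- function(res, heat) {
    sim <- quick_sim(res, heat, n_cycles = 8)
    cycle_average(tibble::tibble(time = sim$time, dps = sim$dps),
                  attr(sim, "protocol"), discard = 3)
  }
  hot20 <- avg_of("20G", TRUE)
  cold20 <- avg_of("20G", FALSE)
  none_hot <- avg_of("none", TRUE)
  d <- align_and_subtract(hot20, cold20)
  j <- dplyr::inner_join(d, none_hot, by = "time", suffix = c("_d", "_n"))
  expect_gt(stats::cor(j$dps_d, j$dps_n), 0.9)
  # additivity: the peak-normalised residual of the decomposition is small
  resid <- j$dps_d - (j$dps_n - stats::median(j$dps_n)) -
    stats::median(j$dps_d)
  expect_lt(sqrt(mean(resid^2)) / max(abs(j$dps_n - stats::median(j$dps_n))),
            0.15)
})
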