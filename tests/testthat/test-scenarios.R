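test_that("corner frequency follows the RC relation", {
  expect_equal(round(corner_frequency(0.196), 2), 0.81)
  expect_equal(round(corner_frequency(0.378), 2), 0.42)
  taus <- c(0.04, 0.1, 0.4, 2)
  expect_true(all(diff(corner_frequency(taus)) < 0))
  expect_error(corner_frequency(0), "positive")
  expect_error(corner_frequency(Inf), "positive")
})

test_that("the filter spec ties tau, resistance and compliance together", {
  spec <- chamber_filter_spec(0.058, v_gas = 1178.59)
  expect_equal(spec$r_leak * spec$c_ch, 0.058)
  expect_equal(spec$fc, 1 / (2 * pi * 0.058))
})

test_that("bias-flow calibration maps sensor units back to known flows", {
  ch <- chamber_config(tau = 0.058)
  cal <- calibrate_flow_from_bias(ch)
  # the calibrated pneumotach gain must equal the leak conductance
  r_leak <- chamber_filter_spec(0.058, ch$v_chamber - alm_config()$v_min)$r_leak
  expect_equal(cal$gain / 60, 1 / r_leak, tolerance = 0.01)
  expect_equal(cal$offset, 0, tolerance = 1e-6)
})

test_that("scenario runs are deterministic and enumerate their grids", {
  a <- run_scenario("component_matrix", n_cycles = 6)
  b <- run_scenario("component_matrix", n_cycles = 6)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$traces, b$traces)
  expect_equal(nrow(a$metrics), 6)
  expect_length(a$traces, 6)
  expect_true(all(c("none_40C", "27G_26C") %in% names(a$traces)))
})

test_that("the table scenario reports the corner-frequency grid", {
  res <- run_scenario("table1")
  expect_equal(nrow(res$metrics), 10)
  expect_equal(res$metrics$fc_printed[res$metrics$tau == 0.103], 1.55)
})

test_that("scenario outputs round-trip through the trace files", {
  out <- withr::local_tempdir()
  res <- run_scenario("closed_mode", out_dir = out, n_cycles = 6)
  files <- list.files(out)
  expect_true("closed_mode_metrics.tsv" %in% files)
  tr_file <- file.path(out, "closed_mode_20G_te100.tsv")
  expect_true(file.exists(tr_file))
  back <- read_traces(tr_file)
  expect_identical(back$dps, res$traces[["20G_te100"]]$dps)
})

test_that("device calibration reads a smaller volume for slow expiration", {
  res <- run_scenario("device_calibration", n_cycles = 6)
  v <- res$metrics
  expect_lt(v$device_v_t_ul[v$t_exp == 0.8], v$device_v_t_ul[v$t_exp == 0.1])
  # both in the vicinity of the mechanical excursion (290 uL)
  expect_true(all(v$device_v_t_ul > 200 & v$device_v_t_ul < 400))
})

test_that("breathing analysis summarises into tidy one-row glances", {
  an <- analyze_breathing(quick_sim("none", TRUE, n_cycles = 6))
  g <- glance(an)
  expect_equal(nrow(g), 1)
  expect_equal(g$f_r, 30, tolerance = 0.01)
  expect_gt(g$adj_v_t_ul, g$v_t_ul)
  expect_equal(g$f_adj,
               conditioning_adjustment(T_L = 313.15, T_C = 299.15)$F_adj)
})

test_that("unknown scenarios are refused", {
  expect_error(run_scenario("imaginary_experiment"))
  expect_equal(nrow(list_scenarios()), 6)
})
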