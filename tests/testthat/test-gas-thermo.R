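test_that("saturation vapor pressure matches reference points and is monotone", {
  # boiling point at standard pressure
  expect_equal(saturation_vapor_pressure(373.15), 760, tolerance = 0.01)
  # body temperature, against an independent evaluation of the Buck formula
  expect_equal(saturation_vapor_pressure(310.15), 47.103009, tolerance = 1e-6)
  expect_gt(saturation_vapor_pressure(299.15), 20)
  # strictly increasing on a 0.1 K grid across the whole domain
  grid <- seq(233.2, 373.5, by = 0.1)
  expect_true(all(diff(saturation_vapor_pressure(grid)) > 0))
  expect_error(saturation_vapor_pressure(200), "range")
  expect_error(saturation_vapor_pressure(400), "range")
})

test_that("volume adjustment factor reproduces the hand evaluation", {
  # independent hand computation of the closed form with the module's own
  # saturation pressure: P_A = 760, Pv_L = sat(313.15), Pv_C = 0,
  # T_C = 299.15, T_L = 313.15
  f <- volume_adjustment_factor(760, saturation_vapor_pressure(313.15), 0,
                                T_L = 313.15, T_C = 299.15)
  expect_equal(f, 8.74829711, tolerance = 1e-8)
  expect_gt(f, 1)
})

test_that("volume adjustment factor is singular for identical gas states", {
  expect_error(volume_adjustment_factor(760, 0, 0, T_L = 300, T_C = 300),
               "singular")
  expect_error(volume_adjustment_factor(760, -1, 0, T_L = 300, T_C = 280))
  expect_error(volume_adjustment_factor(760, 800, 0, T_L = 300, T_C = 280))
})

test_that("adjustment factor decreases as the lung-chamber gap widens", {
  t_c <- 299.15
  t_l <- seq(t_c + 2, t_c + 40, by = 0.5)
  f <- vapply(t_l, function(T_L)
    volume_adjustment_factor(760, 47, 12.6, T_L = T_L, T_C = t_c), numeric(1))
  expect_true(all(diff(f) < 0))
  # diverges approaching the singular limit from the conditioning side
  t_close <- t_c + c(2, 1, 0.5, 0.25)
  f_close <- vapply(t_close, function(T_L)
    volume_adjustment_factor(760, 12.6, 12.6, T_L = T_L, T_C = t_c), numeric(1))
  expect_true(all(diff(f_close) > 0))
})

test_that("adjustment factor equals an independent transcription on random inputs", {
  set.seed(101)
  n <- 200
  P_A <- runif(n, 700, 800)
  T_L <- runif(n, 303, 323)
  T_C <- runif(n, 288, 300)
  Pv_L <- runif(n, 0.8, 1) * saturation_vapor_pressure(T_L)
  Pv_C <- runif(n, 0, 0.8) * saturation_vapor_pressure(T_C)
  oracle <- 1 / (1 - ((P_A - Pv_L) / (P_A - Pv_C)) * (T_C / T_L))
  got <- volume_adjustment_factor(P_A, Pv_L, Pv_C, T_L, T_C)
  expect_equal(got, oracle, tolerance = 1e-13)
})

test_that("gas parcels obey the ideal gas law", {
  p <- parcel_from_state(P = 760, T = 299.15, V = 1000, RH = 0)
  expect_equal(parcel_pressure(p), 760, tolerance = 1e-10)
  # Boyle: halving the volume doubles the pressure
  half <- gas_parcel(p$n_dry, p$n_water, p$T, p$V / 2)
  expect_equal(parcel_pressure(half), 1520, tolerance = 1e-10)
  # Gay-Lussac: pressure scales with temperature at fixed amount and volume
  warm <- gas_parcel(p$n_dry, p$n_water, 313.15, p$V)
  expect_equal(parcel_pressure(warm) / parcel_pressure(p), 313.15 / 299.15,
               tolerance = 1e-10)
  # round trip through (P, T, V) is the identity
  p2 <- parcel_from_state(P = 731.2, T = 305.4, V = 57.3, RH = 0.4)
  expect_equal(parcel_pressure(p2), 731.2, tolerance = 1e-10)
})

test_that("supersaturated parcels are clipped and the excess recorded", {
  sat <- parcel_from_state(P = 760, T = 310.15, V = 10, RH = 1)
  over <- gas_parcel(sat$n_dry, sat$n_water * 1.5, sat$T, sat$V)
  expect_gt(over$condensed, 0)
  pv <- over$n_water * gas_constant()$R_gas * over$T / over$V
  expect_equal(pv, saturation_vapor_pressure(over$T), tolerance = 1e-10)
})

test_that("parcel constructors reject unphysical inputs", {
  expect_error(gas_parcel(1e-3, 0, 300, -1), "positive")
  expect_error(gas_parcel(-1e-3, 0, 300, 1), "non-negative")
  expect_error(parcel_from_state(P = 10, T = 310.15, V = 1, RH = 1), "exceeds")
})

test_that("conditioning adjustment bundles defaults consistently", {
  adj <- conditioning_adjustment(T_L = 313.15, T_C = 299.15)
  expect_s3_class(adj, "conditioning_adjustment")
  expect_equal(adj$Pv_L, saturation_vapor_pressure(313.15))
  expect_equal(adj$Pv_C, 0.5 * saturation_vapor_pressure(299.15))
  expect_gt(adj$F_adj, 1)
})
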