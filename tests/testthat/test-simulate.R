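# Simulation: conservation, oracle agreement, state-variable invariants
# and the trajectory summary metrics.

test_that("zero initial sugar gives a constant trajectory", {
  tr <- simulate_monoculture(ej2_kinetics(), S0 = 0, X0 = 0.45, P0 = 2,
                             opts = sim_options(t_end = 10))
  expect_true(all(tr$biomass_gdcw_L == 0.45))
  expect_true(all(tr$cellobiose_g_L == 0))
  expect_true(all(tr$ethanol_g_L == 2))
})

test_that("yield bookkeeping is conserved without maintenance", {
  k <- ej2_no_maintenance()
  tr <- simulate_monoculture(k, S0 = 40, X0 = 0.45)
  balance <- (40 - tr$cellobiose_g_L) - tr$ethanol_g_L / k$Yps -
    (tr$biomass_gdcw_L - 0.45) / k$Yxs
  expect_lt(max(abs(balance)), 1e-5)
})

test_that("adaptive solver agrees with the fixed-step 4th-order cross-check", {
  k <- ej2_kinetics()
  tr <- simulate_monoculture(k, S0 = 40, X0 = 0.45)
  final <- unlist(tr[nrow(tr), c("biomass_gdcw_L", "cellobiose_g_L",
                                 "ethanol_g_L")])
  oracle <- integrate_fixed_step(k, S0 = 40, X0 = 0.45, dt = 1e-3,
                                 t_end = 48)
  expect_lt(max(abs(final - oracle[c("X", "S", "P")])), 1e-4)
})

test_that("states stay nonnegative, sugars nonincreasing, ethanol nondecreasing", {
  cases <- list(
    simulate_monoculture(ej2_kinetics(), 120, 0.45),
    simulate_monoculture(sr8_kinetics(), 80, 0.45),
    simulate_coculture(coculture_params(S0_c = 40, S0_x = 40,
                                        X0_E = 0.45, X0_S = 0.45)))
  for (tr in cases) {
    m <- as.matrix(as.data.frame(tr))
    expect_true(all(m >= 0))
    expect_true(all(diff(tr$cellobiose_g_L) <= 1e-9))
    expect_true(all(diff(tr$xylose_g_L) <= 1e-9))
    expect_true(all(diff(tr$ethanol_g_L) >= -1e-9))
    expect_true(all(diff(tr$biomass_gdcw_L) >= -1e-9))
  }
})

test_that("halving the solver tolerances barely changes the solution", {
  k <- sr8_kinetics()
  a <- simulate_monoculture(k, 40, 0.45)
  b <- simulate_monoculture(k, 40, 0.45,
                            opts = sim_options(rtol = 5e-9, atol = 5e-11))
  for (cc in c("biomass_gdcw_L", "xylose_g_L", "ethanol_g_L")) {
    rel <- abs(a[[cc]] - b[[cc]]) / pmax(abs(a[[cc]]), 1e-3)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("depletion time interpolates the threshold crossing", {
  t <- seq(0, 24, by = 0.5)
  df <- data.frame(time_h = t, biomass_gdcw_L = 1,
                   cellobiose_g_L = pmax(40 - 2 * t, 0), xylose_g_L = 0,
                   ethanol_g_L = cummax(pmin(2 * t, 20)))
  tr <- fermentation_trajectory(df, "synthetic")
  expect_equal(depletion_time(tr, "cellobiose", threshold = 1), 19.5)
  expect_equal(depletion_time(tr, "cellobiose", threshold = 50), 0)
  # xylose column is identically zero: already below threshold at t = 0
  expect_equal(depletion_time(tr, "xylose", threshold = 0.5), 0)
  expect_error(depletion_time(tr, "glucose"), "arg")
})

test_that("depletion time is NA when the sugar never falls below threshold", {
  df <- data.frame(time_h = 0:10, biomass_gdcw_L = 1,
                   cellobiose_g_L = seq(40, 30, length.out = 11),
                   xylose_g_L = 0, ethanol_g_L = 0)
  tr <- fermentation_trajectory(df, "synthetic")
  expect_true(is.na(depletion_time(tr, "cellobiose", threshold = 1)))
})

test_that("ethanol productivity divides titer by completion time", {
  t <- seq(0, 24, by = 0.5)
  df <- data.frame(time_h = t, biomass_gdcw_L = 1,
                   cellobiose_g_L = pmax(40 - 2 * t, 0), xylose_g_L = 0,
                   ethanol_g_L = pmin(t * 20 / 19.5, 20))
  tr <- fermentation_trajectory(df, "synthetic")
  # completion at the 19.5 h cellobiose crossing, P there = 20
  expect_equal(ethanol_productivity(tr, threshold = 1), 20 / 19.5,
               tolerance = 1e-9)
  flat <- fermentation_trajectory(
    data.frame(time_h = 0:10, biomass_gdcw_L = 1, cellobiose_g_L = 40,
               xylose_g_L = 0, ethanol_g_L = 5), "synthetic")
  expect_equal(ethanol_productivity(flat), 0)
})

test_that("equal-sugar equal-inoculum co-culture depletes both sugars by 24 h", {
  p <- coculture_params(S0_c = 40, S0_x = 40, X0_E = 0.45, X0_S = 0.45)
  tr <- simulate_coculture(p)
  tc <- depletion_time(tr, "cellobiose", 1)
  tx <- depletion_time(tr, "xylose", 1)
  expect_false(is.na(tc))
  expect_false(is.na(tx))
  expect_lt(tc, 24)
  expect_lt(tx, 24)
  # observable biomass equals the sum of the strain compartments
  expect_equal(tr$biomass_gdcw_L,
               tr$biomass_ej2_gdcw_L + tr$biomass_sr8_gdcw_L)
})

test_that("at 80+40 with equal inocula cellobiose lags xylose substantially", {
  p <- coculture_params(S0_c = 80, S0_x = 40, X0_E = 0.45, X0_S = 0.45)
  tr <- simulate_coculture(p)
  tx <- depletion_time(tr, "xylose", 1)
  tc <- depletion_time(tr, "cellobiose", 1)
  expect_false(is.na(tx))
  # cellobiose is still far from done when xylose is consumed
  s_c_at_tx <- approx(tr$time_h, tr$cellobiose_g_L, tx)$y
  expect_gt(s_c_at_tx, 10)
  if (!is.na(tc)) expect_gt(tc, tx + 5)
})

test_that("trajectory validation rejects malformed input", {
  expect_error(fermentation_trajectory(
    data.frame(time_h = c(0, 0), biomass_gdcw_L = 1, ethanol_g_L = 0),
    "simulated"), "strictly increasing")
  expect_error(fermentation_trajectory(
    data.frame(time_h = 0:1, biomass_gdcw_L = c(1, -1), ethanol_g_L = 0),
    "simulated"), "negative")
  expect_error(fermentation_trajectory(
    data.frame(time_h = 0:1, ethanol_g_L = 0), "simulated"),
    "missing required")
})
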