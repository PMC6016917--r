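# Estimation: Lineweaver-Burk initialization, residual pooling,
# least-squares refinement and the analytic Discussion-style helpers.

test_that("two-point Lineweaver-Burk solves match the printed growth constants", {
  # xylose strain: grows 0.136 /h at 10 g/L, 0.149 /h at 40 g/L
  est <- lineweaver_burk(data.frame(S = c(10, 40), mu = c(0.136, 0.149)))
  expect_equal(est[["mu_m"]], 0.1539038, tolerance = 1e-6)
  expect_equal(est[["Ks"]], 1.3164557, tolerance = 1e-6)
  expect_equal(round(est[["mu_m"]], 3), 0.154)
  # cellobiose strain: 0.146 and 0.152 /h
  est2 <- lineweaver_burk(data.frame(S = c(10, 40), mu = c(0.146, 0.152)))
  expect_equal(round(est2[["mu_m"]], 3), 0.154)
})

test_that("Lineweaver-Burk is exact on noiseless Monod data", {
  S <- c(1, 2, 5, 10, 20)
  pts <- data.frame(S = S, mu = 0.2 * S / (2 + S))
  est <- lineweaver_burk(pts)
  expect_equal(est[["mu_m"]], 0.2, tolerance = 1e-10)
  expect_equal(est[["Ks"]], 2, tolerance = 1e-10)
})

test_that("Lineweaver-Burk input validation", {
  expect_error(lineweaver_burk(data.frame(S = 10, mu = 0.1)), "two points")
  expect_error(lineweaver_burk(data.frame(S = c(10, 10),
                                          mu = c(0.1, 0.12))), "coincident")
  expect_error(lineweaver_burk(data.frame(S = c(-1, 10),
                                          mu = c(0.1, 0.12))), "positive")
  # super-Monod acceleration extrapolates to a nonpositive intercept
  expect_error(lineweaver_burk(data.frame(S = c(10, 40),
                                          mu = c(0.1, 0.5))), "intercept")
})

test_that("residual pooling reproduces hand-computed RSS and RMSE", {
  df <- data.frame(time_h = c(0, 10), biomass_gdcw_L = c(1, 2),
                   cellobiose_g_L = c(10, 5), xylose_g_L = 0,
                   ethanol_g_L = c(0, 3))
  model <- fermentation_trajectory(df, "simulated")
  obs <- df
  obs$biomass_gdcw_L <- obs$biomass_gdcw_L + c(1, 0)
  obs$cellobiose_g_L <- obs$cellobiose_g_L - c(2, 0)
  obs$ethanol_g_L <- obs$ethanol_g_L + c(0, 2)
  data <- fermentation_trajectory(obs, "synthetic")
  res <- trajectory_residuals(model, data)
  expect_equal(sort(abs(res[res != 0])), c(1, 2, 2))
  expect_equal(sum(res^2), 9)
  expect_equal(sqrt(sum(res^2) / 3), sqrt(3), tolerance = 1e-12)
  expect_equal(trajectory_residuals(model, model), rep(0, 6))
})

test_that("model trajectory has near-zero residuals on its own noiseless samples", {
  k <- ej2_kinetics()
  d <- noiseless_dataset(k, 40)[[1]]
  m <- simulate_monoculture(k, 40, 0.45)
  res <- trajectory_residuals(m, d)
  expect_lt(sqrt(mean(res^2)), 1e-6)
})

test_that("least-squares refinement recovers production parameters exactly from clean data", {
  k <- toy_monod()
  data <- noiseless_dataset(k, c(10, 30), times = seq(0, 36, by = 3))
  k0 <- k
  k0$vm <- k$vm * 1.5
  k0$Ksp <- k$Ksp * 1.5
  fit <- fit_parameters(data, k0, free = c("vm", "Ksp"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate[["vm"]] - k$vm) / k$vm, 0.01)
  expect_lt(abs(fit$estimate[["Ksp"]] - k$Ksp) / k$Ksp, 0.01)
  expect_equal(fit$rmse, sqrt(fit$rss / fit$n_obs))
  # optimum beats any singly-perturbed restart point
  for (f in c("vm", "Ksp")) {
    k_pert <- fit$kinetics
    k_pert[[f]] <- k_pert[[f]] * 1.1
    res_p <- unlist(lapply(data, function(d) {
      m <- simulate_monoculture(k_pert, attr(d, "info")$S0,
                                attr(d, "info")$X0)
      trajectory_residuals(m, d)
    }))
    expect_lte(fit$rss, sum(res_p^2))
  }
})

test_that("fitting rejects empty data and unknown parameter names", {
  expect_error(fit_parameters(list(), ej2_kinetics()), "empty")
  d <- noiseless_dataset(toy_monod(), 10)
  expect_error(fit_parameters(d, toy_monod(), free = "nope"), "unknown")
})

test_that("residual pooling is invariant to dataset order and additive in RSS", {
  k <- toy_monod()
  data <- noiseless_dataset(k, c(10, 30))
  k1 <- k
  k1$vm <- k$vm * 1.2
  rss_of <- function(ds) sum(unlist(lapply(ds, function(d) {
    m <- simulate_monoculture(k1, attr(d, "info")$S0, attr(d, "info")$X0)
    trajectory_residuals(m, d)
  }))^2)
  expect_equal(rss_of(data), rss_of(rev(data)), tolerance = 1e-10)
  expect_equal(rss_of(data), rss_of(data[1]) + rss_of(data[2]),
               tolerance = 1e-10)
})

test_that("variant comparison declares the generating model family the winner", {
  # generated without any substrate inhibition: the lean variant wins
  k_no <- sr8_kinetics()
  d_no <- noiseless_dataset(k_no, c(20, 60), times = seq(0, 36, by = 3))
  tab <- compare_variants(d_no, k_no)
  expect_setequal(tab$variant, c("with_both", "without_Ki", "without_Kip",
                                 "without_both"))
  expect_true(all(tab$rmse[tab$variant == "without_both"] <=
                  tab$rmse + 1e-9))
  # generated with strong growth substrate inhibition: keeping Ki wins
  k_si <- ej2_kinetics()
  k_si$Ki <- 50
  d_si <- noiseless_dataset(k_si, c(20, 60), times = seq(0, 36, by = 3))
  tab2 <- compare_variants(d_si, k_si,
                           variants = c("with_both", "without_Ki"))
  expect_lt(tab2$rmse[tab2$variant == "with_both"],
            tab2$rmse[tab2$variant == "without_Ki"])
  # single-variant request gives a one-row table
  tab3 <- compare_variants(d_no, k_no, variants = "without_both")
  expect_equal(nrow(tab3), 1L)
})

test_that("plateau truncation drops post-stall samples", {
  t <- seq(0, 30, by = 3)
  s <- c(40, 30, 20, 12, 6, 3, 2.2, 2.1, 2.05, 2.0, 2.0)
  df <- data.frame(time_h = t, biomass_gdcw_L = 1, cellobiose_g_L = 0,
                   xylose_g_L = s, ethanol_g_L = seq(0, 10, length.out = 11))
  tr <- fermentation_trajectory(df, "synthetic")
  cut <- truncate_at_plateau(tr, "xylose", delta = 0.1)
  expect_lt(nrow(cut), nrow(tr))
  # the retained part still shows active consumption
  s_kept <- cut$xylose_g_L
  expect_gt(s_kept[length(s_kept) - 2] - s_kept[length(s_kept)], 0.09)
})

test_that("inhibition thresholds follow complete conversion at the yield basis", {
  ej2 <- ej2_kinetics()
  thr <- inhibition_thresholds(ej2, Pm_exp = 69, Yps_basis = 0.5)
  expect_equal(thr[["S_growth_stop"]], 138)
  expect_equal(thr[["S_production_stop"]], 200)
  sr8 <- sr8_kinetics()
  thr2 <- inhibition_thresholds(sr8, Pm_exp = 85, Yps_basis = 0.35)
  expect_equal(thr2[["S_growth_stop"]], 242.8571, tolerance = 1e-6)
  expect_gt(thr2[["S_growth_stop"]], 240)
  k1 <- toy_monod()
  expect_equal(inhibition_thresholds(k1, 1, 1)[["S_growth_stop"]], 1)
  expect_error(inhibition_thresholds(ej2, -1, 0.5), "> 0")
})

test_that("theoretical yield fraction is a simple percentage", {
  expect_equal(theoretical_yield_fraction(0.5, 0.511), 97.84736,
               tolerance = 1e-6)
  expect_equal(round(theoretical_yield_fraction(0.5, 0.511)), 98)
  expect_equal(theoretical_yield_fraction(0.37, 0.37), 100)
  expect_equal(theoretical_yield_fraction(0.25, 0.5), 50)
  expect_error(theoretical_yield_fraction(0.5, 0), "> 0")
})
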