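test_that("the truth model is continuous, monotone, and LQ below the tail", {
  cfg <- sim_config()
  cfgT <- sim_config(tail = list(transition_dose = 6, tail_slope = 1.2))
  expect_equal(true_sf(cfg, 1, 0), 1)
  d <- seq(0, 15, by = 0.05)
  expect_equal(true_sf(cfgT, 1, d[d <= 6]), true_sf(cfg, 1, d[d <= 6]))
  expect_equal(true_sf(cfgT, 1, 6), true_sf(cfg, 1, 6), tolerance = 1e-12)
  expect_true(all(diff(true_sf(cfgT, 1, d)) < 0))
  # beyond the transition the tail survives more than the LQ extrapolation
  expect_gt(true_sf(cfgT, 1, 8), true_sf(cfg, 1, 8))
  # fractions multiply in the tail model too
  expect_equal(true_sf(cfgT, 2, 8), true_sf(cfgT, 1, 8)^2, tolerance = 1e-12)
})

test_that("simulated assays are reproducible and respect the binomial law", {
  cfg <- sim_config()
  expect_identical(simulate_assay(cfg, seed = 5), simulate_assay(cfg, seed = 5))

  # binomial oracle: mean colony count at one dose across many wells
  cfg1 <- sim_config(schedules = tibble::tibble(n_fractions = 1,
                                                dose_per_fraction_gy = 2),
                     replicates = 5000)
  rec <- simulate_assay(cfg1, seed = 9)
  p <- cfg1$pe0 * true_sf(cfg1, 1, 2)
  mu <- cfg1$cells_seeded * p
  se <- sqrt(cfg1$cells_seeded * p * (1 - p) / nrow(rec))
  expect_lt(abs(mean(rec$colonies) - mu), 3 * se)

  # a dose far beyond any survival yields empty wells
  cfg0 <- sim_config(schedules = tibble::tibble(n_fractions = 1,
                                                dose_per_fraction_gy = c(0, 500)))
  rec0 <- simulate_assay(cfg0, seed = 2)
  expect_true(all(rec0$colonies[rec0$dose_per_fraction_gy == 500] == 0))
})

test_that("parameter recovery approaches truth in the noise-free limit", {
  cfg <- sim_config(cells_seeded = 1e7, pe0 = 1,
                    schedules = tibble::tibble(
                      n_fractions = 1,
                      dose_per_fraction_gy = c(0, 1, 2, 4, 6)))
  st <- parameter_recovery_study(cfg, n_sims = 5, seed = 4)
  expect_true(all(abs(st$summary$rel_bias) < 0.001))
  expect_equal(st$n_dropped, 0L)

  one <- parameter_recovery_study(cfg, n_sims = 1, seed = 4)
  expect_true(one$degenerate)
})

test_that("overestimation demo gives exact agreement under LQ truth", {
  demo <- overestimation_demo(sim_config())
  expect_equal(demo$rows$calculated_exact, demo$rows$measured_exact,
               tolerance = 1e-6)
  expect_true(all(demo$rows$cm == 100L))
})

test_that("a high-dose tail makes the BED conversion overestimate", {
  cfg <- sim_config(tail = default_tail())
  fitted_ratio <- overestimation_demo(cfg)$fit$ratio
  demo <- overestimation_demo(cfg, inflated_ratios = 2 * fitted_ratio)
  r6 <- demo$rows[demo$rows$dose_per_fraction_gy == 6, ]
  # the 6 Gy x 2 arm's equivalent dose lies beyond the transition:
  # calculated underestimates measured at the fitted ratio
  at_fit <- r6[r6$ratio_source == "fitted", ]
  at_inf <- r6[r6$ratio_source == "supplied", ]
  expect_lt(at_fit$cm, 100L)
  expect_lt(at_fit$calculated_exact, at_fit$measured_exact)
  # recomputing at an inflated alpha/beta moves C/M up toward 100
  expect_gt(at_inf$cm, at_fit$cm)
})

test_that("growth simulation is deterministic exponential regrowth with kill", {
  gcfg <- growth_config(noise_cv = 0)
  traj <- simulate_growth(gcfg, seed = 1)
  ctrl <- traj[traj$group == "control", ]
  expect_equal(ctrl$volume_true,
               gcfg$v0 * exp(gcfg$growth_rate * ctrl$day), tolerance = 1e-12)
  expect_equal(ctrl$volume_measured, ctrl$volume_true)
  # truncated at the first measurement reaching the endpoint volume
  expect_true(all(ctrl$volume_true[-nrow(ctrl)] < gcfg$endpoint_volume))
  # identical with the same seed when noisy
  g2 <- growth_config(noise_cv = 0.1)
  expect_identical(simulate_growth(g2, seed = 8), simulate_growth(g2, seed = 8))
})

test_that("log-kill ordering of schedules follows their BED ranking", {
  expect_equal(ellipsoid_volume(1, 1), 0.5)
  # cumulative log kill is alpha * BED at the exact fitted ratio
  alpha <- pc3$alpha; beta <- pc3$beta
  r <- alpha_beta_ratio(alpha, beta)
  kill <- function(n, d) n * (alpha * d + beta * d^2)
  expect_equal(kill(10, 2) / alpha, bed(10, 2, r), tolerance = 1e-12)
  expect_equal(kill(1, 8) / alpha, bed(1, 8, r), tolerance = 1e-12)
  expect_equal(kill(10, 2) / alpha, 42.9, tolerance = 2e-3)
  expect_equal(kill(1, 8) / alpha, 44.65, tolerance = 2e-3)
  expect_lt(kill(10, 2), kill(1, 8))

  # the noiseless simulator's terminal suppression obeys the same order
  gcfg <- growth_config(noise_cv = 0, schedules = tibble::tibble(
    group = c("2Gy x 10", "8Gy x 1"),
    n_fractions = c(10, 1), dose_per_fraction_gy = c(2, 8)))
  traj <- simulate_growth(gcfg)
  last_day <- max(traj$day[traj$group == "2Gy x 10"])
  v <- function(g) traj$volume_true[traj$group == g & traj$day == 30]
  expect_gt(v("2Gy x 10"), v("8Gy x 1"))
})
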