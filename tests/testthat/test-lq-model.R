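test_that("two exact points solve the LQ system in closed form", {
  # alpha + beta = 0.23 and 2 alpha + 4 beta = 0.62 => alpha 0.15, beta 0.08
  pts <- tibble::tibble(dose = c(0, 1, 2), sf = c(1, exp(-0.23), exp(-0.62)))
  fit <- fit_lq(pts)
  expect_equal(fit$alpha, 0.15, tolerance = 1e-12)
  expect_equal(fit$beta, 0.08, tolerance = 1e-12)
})

test_that("noise-free curves return their generating parameters", {
  d <- c(0, 1, 2, 4, 6, 8, 12)
  for (p in list(pc3, du145)) {
    pts <- tibble::tibble(dose = d, sf = predict_sf(p$alpha, p$beta, 1, d))
    fit <- fit_lq(pts)
    expect_equal(fit$alpha, p$alpha, tolerance = 1e-9)
    expect_equal(fit$beta, p$beta, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(fit$alpha_ci[1] <= fit$alpha && fit$alpha <= fit$alpha_ci[2])
  }
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_lq(tibble::tibble(dose = c(0, 2), sf = c(1, 0.5))),
               "distinct")
  expect_error(fit_lq(tibble::tibble(dose = c(4, 4, 4), sf = c(0.2, 0.21, 0.19))),
               "singular")
  expect_error(fit_lq(tibble::tibble(dose = c(1, 2, 4), sf = c(0.9, 0, 0.2))),
               "\\(0, 1\\]")
})

test_that("weighted and unweighted fits coincide under equal errors", {
  d <- c(1, 2, 4, 6, 8)
  set.seed(3)
  pts <- tibble::tibble(dose = d,
                        sf = predict_sf(0.15, 0.08, 1, d) * exp(rnorm(5, 0, 0.05)),
                        se = NA)
  pts$se <- 0.04 * pts$sf # constant se on the log scale
  fw <- fit_lq(pts, weights = TRUE)
  fu <- fit_lq(pts, weights = FALSE)
  expect_equal(fw$alpha, fu$alpha, tolerance = 1e-9)
  expect_equal(fw$beta, fu$beta, tolerance = 1e-9)
  expect_error(fit_lq(pts[, c("dose", "sf")], weights = TRUE), "se")
})

test_that("negative estimates are clipped to zero with a warning", {
  # concave-up survival (beta < 0 truth) forces a negative beta estimate
  d <- c(1, 4, 8, 12)
  pts <- tibble::tibble(dose = d, sf = exp(-(0.5 * d - 0.01 * d^2)))
  expect_warning(fit <- fit_lq(pts), "clipped")
  expect_identical(fit$beta, 0)
  expect_true(fit$clipped)
})

test_that("survival prediction obeys the repair-between-fractions identity", {
  expect_equal(predict_sf(0.15, 0.08, 1, 0), 1)
  expect_equal(predict_sf(0.1461, 0.08366, 1, 7.19),
               exp(-(0.1461 * 7.19 + 0.08366 * 7.19^2)), tolerance = 1e-12)
  expect_equal(predict_sf(0.1461, 0.08366, 1, 7.19), 0.00463,
               tolerance = 1e-3)
  for (ab in list(c(0.1461, 0.08366), c(0.2, 0), c(0, 0.05))) {
    expect_equal(predict_sf(ab[1], ab[2], 2, 4),
                 predict_sf(ab[1], ab[2], 1, 4)^2, tolerance = 1e-12)
  }
  # strictly decreasing in dose whenever alpha + beta > 0
  d <- seq(0, 20, by = 0.25)
  expect_true(all(diff(predict_sf(0.1461, 0.08366, 1, d)) < 0))
  expect_error(predict_sf(0.15, 0.08, 1, -1), ">= 0")
})

test_that("curve inversion is the exact inverse of prediction", {
  expect_equal(invert_single_dose(0.15, 0.08, 1), 0)
  expect_equal(invert_single_dose(0.2, 0, exp(-1)), 5)
  d <- seq(0, 20, by = 0.5)
  for (p in list(pc3, du145, list(alpha = 0.3, beta = 0.001))) {
    back <- invert_single_dose(p$alpha, p$beta,
                               predict_sf(p$alpha, p$beta, 1, d))
    expect_equal(back, d, tolerance = 1e-9)
  }
  expect_error(invert_single_dose(0.15, 0.08, 1.2), "\\(0, 1\\]")
  expect_error(invert_single_dose(0, 0, 0.5), "no dose")
})

test_that("alpha/beta ratio reproduces the published values", {
  expect_equal(round(alpha_beta_ratio(pc3$alpha, pc3$beta), 2), 1.75)
  expect_equal(round(alpha_beta_ratio(du145$alpha, du145$beta), 2), 3.78)
  expect_equal(alpha_beta_ratio(0, 0.08), 0)
  expect_identical(alpha_beta_ratio(0.2, 0), Inf)
})

test_that("printing a fit reports the headline quantities", {
  pts <- tibble::tibble(dose = c(0, 1, 2, 4, 6, 8, 12))
  pts$sf <- predict_sf(pc3$alpha, pc3$beta, 1, pts$dose)
  expect_output(print(fit_lq(pts)), "alpha/beta = 1.75")
})
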