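test_that("plating efficiency is the colony fraction and rejects bad counts", {
  expect_equal(plating_efficiency(50, 500), 0.10)
  expect_equal(plating_efficiency(0, 500), 0)
  expect_equal(plating_efficiency(500, 500), 1)
  # scale-free: same multiple of colonies and seeded leaves PE unchanged
  expect_equal(plating_efficiency(50 * 7, 500 * 7),
               plating_efficiency(50, 500))
  expect_error(plating_efficiency(10, 0), "positive")
  expect_error(plating_efficiency(501, 500), "exceed")
})

test_that("surviving fraction divides plating efficiencies with guard rails", {
  expect_equal(surviving_fraction(0.05, 0.10), 0.5)
  expect_equal(surviving_fraction(0.10, 0.10), 1)
  expect_equal(surviving_fraction(0, 0.10), 0)
  expect_warning(sf <- surviving_fraction(0.12, 0.10), "> 1")
  expect_equal(sf, 1.2)
  expect_error(surviving_fraction(0.05, 0), "> 0")
})

test_that("assay CSV round trip preserves records and validates rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- toy_assay()
  write_assay_table(rec, path)
  back <- read_assay_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  bad <- rec
  bad$colonies[2] <- 2000 # exceeds cells seeded
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_assay_table(path2), "row\\(s\\) 2")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("cell_line", "n_fractions", "dose_per_fraction_gy",
                     "cells_seeded", "colonies", "replicate"),
                   collapse = ","), empty)
  expect_warning(out <- read_assay_table(empty), "empty")
  expect_equal(nrow(out), 0)

  expect_error(read_assay_table(withr::local_tempfile()), "not found")
})

test_that("replicate aggregation uses same-replicate controls", {
  pts <- aggregate_replicates(toy_assay())
  irr <- pts[pts$dose_per_fraction_gy == 4, ]
  expect_equal(irr$sf, 0.5)
  expect_equal(irr$se, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  expect_equal(irr$n_replicates, 3L)
  ctrl <- pts[pts$dose_per_fraction_gy == 0, ]
  expect_equal(ctrl$sf, 1)
  expect_true(is.na(ctrl$se))

  # single replicate: se reported absent
  one <- toy_assay()[c(1, 4), ]
  pts1 <- aggregate_replicates(one)
  expect_true(is.na(pts1$se[pts1$dose_per_fraction_gy == 4]))

  # no control group is an error
  expect_error(aggregate_replicates(toy_assay()[4:6, ]), "control")
})

test_that("aggregation is invariant to record order and flags dead arms", {
  rec <- toy_assay()
  set.seed(7)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(aggregate_replicates(shuffled), aggregate_replicates(rec))

  dead <- rec
  dead$colonies[4:6] <- 0
  expect_warning(pts <- aggregate_replicates(dead), "excluded")
  expect_false(any(pts$dose_per_fraction_gy == 4))
})

test_that("pooled-control fallback covers replicates without their own control", {
  rec <- toy_assay()
  rec <- rec[-3, ] # R3 has no control well
  pts <- aggregate_replicates(rec)
  irr <- pts[pts$dose_per_fraction_gy == 4, ]
  # R1, R2 use own control PE 0.1; R3 uses pooled control 200/2000 = 0.1
  expect_equal(irr$sf, 0.5)
})

test_that("aggregated mean survival matches the generator truth", {
  # Monte-Carlo oracle: many replicates at one dose; the aggregated mean
  # SF must land within 3 standard errors of the generating curve.
  cfg <- sim_config(schedules = tibble::tibble(n_fractions = c(1, 1),
                                               dose_per_fraction_gy = c(0, 4)),
                    replicates = 200)
  rec <- simulate_assay(cfg, seed = 11)
  pts <- aggregate_replicates(rec)
  irr <- pts[pts$dose_per_fraction_gy == 4, ]
  truth <- true_sf(cfg, 1, 4)
  expect_lt(abs(irr$sf - truth), 3 * irr$se)
})
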