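#' Configuration for a simulated clonogenic assay
#'
#' Defaults mirror the experiment the analysis targets: a 6-well-plate
#' colony assay on a prostate-cancer line, single doses 0, 1, 2, 4, 6, 8,
#' 12 Gy plus fractionated arms 4 Gy x 2 and 6 Gy x 2 with complete
#' inter-fraction repair, 2000 cells per well, 3 replicates, baseline
#' plating efficiency 0.3, and LQ truth alpha = 0.1461/Gy,
#' beta = 0.08366/Gy^2.
#'
#' `tail` switches the truth model to LQ-with-linear-tail: per fraction,
#' `ln S(d)` follows the LQ curve up to `transition_dose` and continues
#' linearly with slope `-tail_slope` beyond it (continuous at the
#' transition). This is a minimal stand-in for the nearly-linear
#' high-dose behaviour of universal-survival-curve-type models.
#'
#' @param alpha Linear kill coefficient, 1/Gy.
#' @param beta Quadratic kill coefficient, 1/Gy^2.
#' @param pe0 Baseline plating efficiency in `(0, 1]`.
#' @param cells_seeded Cells per well: a scalar, or a vector with one
#'   entry per schedule row.
#' @param schedules Tibble with `n_fractions`, `dose_per_fraction_gy`.
#' @param replicates Number of replicate wells per schedule (`>= 1`).
#' @param cell_line Label written into simulated records.
#' @param tail `NULL` for pure LQ, or `list(transition_dose = , tail_slope
#'   = )` with both positive (Gy and 1/Gy).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(alpha = 0.1461, beta = 0.08366, pe0 = 0.3,
                       cells_seeded = 2000,
                       schedules = default_assay_schedules(),
                       replicates = 3, cell_line = "SIM", tail = NULL) {
  schedules <- tibble::as_tibble(schedules)
  stopifnot(alpha >= 0, beta >= 0, pe0 > 0, pe0 <= 1, replicates >= 1,
            all(cells_seeded >= 1),
            length(cells_seeded) %in% c(1L, nrow(schedules)))
  if (!is.null(tail)) {
    stopifnot(is.list(tail), tail$transition_dose > 0, tail$tail_slope > 0)
  }
  structure(list(alpha = alpha, beta = beta, pe0 = pe0,
                 cells_seeded = cells_seeded, schedules = schedules,
                 replicates = as.integer(replicates),
                 cell_line = cell_line, tail = tail),
            class = "sim_config")
}

#' Default LQ-linear-tail truth parameters
#'
#' A universal-survival-curve-like high-dose tail: transition at 6 Gy and
#' final log-kill slope 0.8/Gy (equivalently D0 = 1.25 Gy), both typical
#' of published high-dose survival data.
#'
#' @return `list(transition_dose = 6, tail_slope = 0.8)`.
#' @export
default_tail <- function() {
  list(transition_dose = 6, tail_slope = 0.8)
}

#' Default assay design: single doses 0-12 Gy plus two fractionated arms
#' @return Tibble of schedules.
#' @export
default_assay_schedules <- function() {
  tibble::tibble(
    n_fractions = c(1, 1, 1, 1, 1, 1, 1, 2, 2),
    dose_per_fraction_gy = c(0, 1, 2, 4, 6, 8, 12, 4, 6)
  )
}

#' True surviving fraction under the configured truth model
#'
#' Pure LQ: `S = exp(n * (-alpha d - beta d^2))`. With a tail, the
#' per-fraction log-survival follows LQ up to the transition dose `dT`
#' and continues linearly, `ln S(d) = ln S(dT) - s (d - dT)` for
#' `d > dT`; fractions multiply (complete inter-fraction repair) in both
#' cases.
#'
#' @param config A [sim_config()].
#' @param n Number of fractions (`>= 1`).
#' @param d Dose per fraction, Gy (vectorised).
#' @return Surviving fraction(s).
#' @export
true_sf <- function(config, n = 1, d) {
  stopifnot(inherits(config, "sim_config"), n >= 1, all(d >= 0))
  lq <- -config$alpha * d - config$beta * d^2
  if (is.null(config$tail)) {
    ln1 <- lq
  } else {
    dT <- config$tail$transition_dose
    s <- config$tail$tail_slope
    ln_at_T <- -config$alpha * dT - config$beta * dT^2
    ln1 <- ifelse(d <= dT, lq, ln_at_T - s * (d - dT))
  }
  exp(n * ln1)
}

#' Simulate a clonogenic assay
#'
#' Each well's colony count is drawn binomially with `cells_seeded`
#' trials and success probability `pe0 * true_sf` (binomial rather than
#' Poisson so counts respect the seeded-cell ceiling; at realistic
#' plating efficiencies the two are indistinguishable). Output is
#' bit-for-bit reproducible given `(seed, config)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return Tibble of assay records (same columns as
#'   [read_assay_table()]).
#' @export
simulate_assay <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sch <- config$schedules
  seeded <- rep(config$cells_seeded, length.out = nrow(sch))
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    p <- config$pe0 * true_sf(config, sch$n_fractions[i],
                              sch$dose_per_fraction_gy[i])
    tibble::tibble(
      cell_line = config$cell_line,
      n_fractions = sch$n_fractions[i],
      dose_per_fraction_gy = sch$dose_per_fraction_gy[i],
      cells_seeded = seeded[i],
      colonies = stats::rbinom(config$replicates, size = seeded[i], prob = p),
      replicate = paste0("R", seq_len(config$replicates))
    )
  })
  dplyr::bind_rows(rows)
}

#' Monte-Carlo parameter-recovery study for the LQ fit
#'
#' Repeats simulate -> aggregate -> fit and summarises how well the LQ
#' parameters are recovered: mean bias, relative bias, RMSE, and coverage
#' of the 95% confidence intervals for alpha and beta, plus the mean
#' fitted alpha/beta ratio. Simulations in which fewer than 3 distinct
#' positive doses survive (all-zero colony counts at too many doses) are
#' dropped and counted.
#'
#' @param config A [sim_config()] without tail, spanning at least 4
#'   distinct single doses.
#' @param n_sims Number of simulated assays.
#' @param seed Integer seed for the whole study.
#' @param weights Passed to [fit_lq()].
#' @return List with `summary` (tibble: one row per parameter with
#'   `truth`, `mean_est`, `bias`, `rel_bias`, `rmse`, `ci_coverage`),
#'   `ratio_mean`, `n_sims`, `n_dropped`, and `degenerate` (`TRUE` when
#'   `n_sims == 1`, where variance-based fields are undefined).
#' @export
parameter_recovery_study <- function(config, n_sims = 500, seed = 1,
                                     weights = FALSE) {
  stopifnot(inherits(config, "sim_config"), is.null(config$tail))
  singles <- config$schedules$dose_per_fraction_gy[
    config$schedules$n_fractions == 1]
  stopifnot(length(unique(singles[singles > 0])) >= 4)
  set.seed(seed)
  est <- matrix(NA_real_, n_sims, 2, dimnames = list(NULL, c("alpha", "beta")))
  cover <- matrix(NA, n_sims, 2, dimnames = list(NULL, c("alpha", "beta")))
  ratio <- rep(NA_real_, n_sims)
  dropped <- 0L
  for (i in seq_len(n_sims)) {
    rec <- simulate_assay(config, seed = NULL)
    pts <- suppressWarnings(aggregate_replicates(rec))
    ok <- tryCatch({
      fit <- suppressWarnings(fit_lq(pts, weights = weights))
      est[i, ] <- c(fit$alpha, fit$beta)
      ratio[i] <- fit$ratio
      cover[i, "alpha"] <- fit$alpha_ci[1] <= config$alpha &&
        config$alpha <= fit$alpha_ci[2]
      cover[i, "beta"] <- fit$beta_ci[1] <= config$beta &&
        config$beta <= fit$beta_ci[2]
      TRUE
    }, error = function(e) FALSE)
    if (!ok) dropped <- dropped + 1L
  }
  keep <- stats::complete.cases(est)
  est <- est[keep, , drop = FALSE]
  cover <- cover[keep, , drop = FALSE]
  truth <- c(alpha = config$alpha, beta = config$beta)
  summarise_par <- function(p) {
    e <- est[, p]
    tr <- truth[[p]]
    tibble::tibble(
      parameter = p,
      truth = tr,
      mean_est = mean(e),
      bias = mean(e) - tr,
      rel_bias = (mean(e) - tr) / tr,
      rmse = sqrt(mean((e - tr)^2)),
      ci_coverage = mean(cover[, p])
    )
  }
  list(
    summary = dplyr::bind_rows(lapply(c("alpha", "beta"), summarise_par)),
    ratio_mean = mean(ratio[keep & is.finite(ratio)]),
    n_sims = n_sims,
    n_used = sum(keep),
    n_dropped = dropped,
    degenerate = n_sims == 1
  )
}

#' Demonstrate BED overestimation under a misspecified survival curve
#'
#' The mechanism study, run noise-free so every deviation is attributable
#' to model misspecification rather than sampling: the exact surviving
#' fractions of the config's single-dose schedules (under the configured
#' truth model, tail or not) are fitted with the LQ model, and each
#' fractionated schedule in the config is then converted to an equivalent
#' single dose two ways — "calculated" by BED isoeffect algebra at the
#' fitted alpha/beta ratio (and at any `inflated_ratios` supplied), and
#' "measured" by inverting the fitted curve at the truth model's true
#' fractionated survival.
#'
#' Under pure LQ truth the two routes solve the same quadratic and C/M is
#' exactly 100; with a linear tail the fitted curve overstates the
#' effectiveness of large single doses and C/M falls below 100, moving
#' back toward 100 as the conversion ratio is inflated.
#'
#' @param config A [sim_config()]; fractionated schedules should keep
#'   `d <= transition_dose` when a tail is present.
#' @param inflated_ratios Extra alpha/beta ratios (Gy) at which to
#'   recompute the conversion, besides the fitted ratio.
#' @return List with `fit` (the `lq_fit`) and `rows`: a tibble with
#'   `n_fractions`, `dose_per_fraction_gy`, `ratio`, `ratio_source`
#'   (`"fitted"` or `"supplied"`), `calculated_exact`, `measured_exact`,
#'   `calculated`, `measured`, `cm`.
#' @export
overestimation_demo <- function(config, inflated_ratios = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sch <- config$schedules
  singles <- sch[sch$n_fractions == 1 & sch$dose_per_fraction_gy > 0, ]
  frac <- sch[sch$n_fractions > 1, ]
  if (nrow(frac) == 0) {
    stop("config has no fractionated schedules to convert", call. = FALSE)
  }
  pts <- tibble::tibble(
    dose_per_fraction_gy = singles$dose_per_fraction_gy,
    sf = true_sf(config, 1, singles$dose_per_fraction_gy)
  )
  fit <- suppressWarnings(fit_lq(pts))
  ratios <- tibble::tibble(
    ratio = c(fit$ratio, inflated_ratios),
    ratio_source = c("fitted", rep("supplied", length(inflated_ratios)))
  )
  rows <- lapply(seq_len(nrow(frac)), function(i) {
    n1 <- frac$n_fractions[i]
    d1 <- frac$dose_per_fraction_gy[i]
    sf_true <- true_sf(config, n1, d1)
    meas <- measured_equivalent_dose(fit, sf_true)
    calc <- equivalent_dose_per_fraction(n1, d1, n2 = 1,
                                         ratio = ratios$ratio)
    tibble::tibble(
      n_fractions = n1, dose_per_fraction_gy = d1,
      ratio = ratios$ratio, ratio_source = ratios$ratio_source,
      calculated_exact = calc, measured_exact = meas,
      calculated = round_half_away(calc, 2),
      measured = round_half_away(meas, 2),
      cm = cm_percent(round_half_away(calc, 2), meas)
    )
  })
  list(fit = fit, rows = dplyr::bind_rows(rows))
}

#' Configuration for the toy xenograft growth simulator
#'
#' Deterministic exponential regrowth with an instantaneous
#' multiplicative kill (the LQ per-fraction surviving fraction) on each
#' irradiation day, one fraction per day starting at day 0, optional
#' lognormal measurement noise, and truncation at the sacrifice volume.
#' Defaults: 0.09 cm^3 at randomisation (short diameter ~0.5 cm),
#' doubling time ~5 days, measurement every 3 days, 2 cm^3 endpoint.
#'
#' @param v0 Initial tumour volume, cm^3.
#' @param growth_rate Exponential growth rate, per day.
#' @param schedules Tibble with `group`, `n_fractions`,
#'   `dose_per_fraction_gy` (a zero-dose row is the control arm).
#' @param alpha,beta LQ kill parameters (1/Gy, 1/Gy^2).
#' @param measure_interval Days between volume measurements.
#' @param endpoint_volume Sacrifice volume, cm^3 (`> v0`).
#' @param noise_cv Coefficient of variation of the lognormal measurement
#'   noise (0 for noiseless).
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(v0 = 0.09, growth_rate = 0.14,
                          schedules = default_growth_schedules(),
                          alpha = 0.1461, beta = 0.08366,
                          measure_interval = 3, endpoint_volume = 2,
                          noise_cv = 0.1) {
  schedules <- tibble::as_tibble(schedules)
  stopifnot(v0 > 0, growth_rate > 0, endpoint_volume > v0,
            measure_interval >= 1, noise_cv >= 0, alpha >= 0, beta >= 0)
  structure(list(v0 = v0, growth_rate = growth_rate, schedules = schedules,
                 alpha = alpha, beta = beta,
                 measure_interval = measure_interval,
                 endpoint_volume = endpoint_volume, noise_cv = noise_cv),
            class = "growth_config")
}

#' Default xenograft arms: control plus five fractionation schemes
#' @return Tibble of groups.
#' @export
default_growth_schedules <- function() {
  tibble::tibble(
    group = c("control", "2Gy x 10", "3Gy x 5", "3Gy x 6",
              "8Gy x 1", "8Gy x 2"),
    n_fractions = c(1, 10, 5, 6, 1, 2),
    dose_per_fraction_gy = c(0, 2, 3, 3, 8, 8)
  )
}

#' Ellipsoid tumour-volume approximation
#'
#' `V = length * width^2 / 2`, the standard caliper formula.
#'
#' @param length Tumour length, cm.
#' @param width Tumour width, cm.
#' @return Volume in cm^3.
#' @examples
#' ellipsoid_volume(1, 1) # 0.5
#' @export
ellipsoid_volume <- function(length, width) {
  stopifnot(all(length >= 0), all(width >= 0))
  length * width^2 / 2
}

#' Simulate xenograft growth curves under fractionated irradiation
#'
#' Volume follows `V(t) = v0 * exp(g t) * prod(SF)` over the fractions
#' delivered by day `t` (one per day from day 0). Measurements are taken
#' every `measure_interval` days with multiplicative lognormal noise of
#' coefficient of variation `noise_cv`; a group's trajectory stops at the
#' first measurement whose true volume reaches `endpoint_volume`.
#'
#' @param config A [growth_config()].
#' @param seed Integer RNG seed (only relevant when `noise_cv > 0`).
#' @param max_days Safety cap on simulated days.
#' @return Tibble with `group`, `day`, `volume_true`, `volume_measured`
#'   (cm^3).
#' @export
simulate_growth <- function(config, seed = NULL, max_days = 365) {
  stopifnot(inherits(config, "growth_config"))
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  rows <- lapply(seq_len(nrow(config$schedules)), function(i) {
    n <- config$schedules$n_fractions[i]
    d <- config$schedules$dose_per_fraction_gy[i]
    sf1 <- predict_sf(config$alpha, config$beta, n = 1, d = d)
    days <- seq(0, max_days, by = config$measure_interval)
    # fractions delivered strictly before the measurement moment on
    # irradiation days count; day 0 is measured pre-treatment
    frac_done <- pmin(pmax(days, 0), n)
    v_true <- config$v0 * exp(config$growth_rate * days) * sf1^frac_done
    stop_at <- which(v_true >= config$endpoint_volume)
    if (length(stop_at) > 0) {
      keep <- seq_len(stop_at[1])
      days <- days[keep]; v_true <- v_true[keep]
    }
    noise <- if (config$noise_cv > 0) {
      stats::rlnorm(length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(days))
    tibble::tibble(group = config$schedules$group[i], day = days,
                   volume_true = v_true,
                   volume_measured = v_true * noise)
  })
  dplyr::bind_rows(rows)
}
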