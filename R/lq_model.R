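#' Fit the linear-quadratic survival model
#'
#' Fits `ln S = -alpha * d - beta * d^2` to single-dose survival points by
#' least squares in the log domain with no intercept, so the curve is
#' forced through `S(0) = 1`. Because the model is linear in the
#' regressors `(-d, -d^2)` the fit is closed-form and reproducible; it is
#' carried out with [stats::lm()]. Zero-dose points are accepted but do
#' not enter the regression (they have zero regressors and zero residual
#' in a through-origin model, so they carry no information).
#'
#' With `weights = TRUE` each point is weighted by the inverse variance of
#' `ln sf` obtained from the delta method, `se_ln = se / sf`. 95%
#' confidence intervals are asymptotic, `estimate +/- t(0.975, df) * SE`.
#' `r_squared` uses the through-origin convention `1 - SSR / sum(y^2)` on
#' the log scale. Negative parameter estimates (possible under extreme
#' noise) are clipped to 0 with a warning.
#'
#' @param points Tibble with columns `dose_per_fraction_gy` (or `dose`),
#'   `sf` and optionally `se` and `n_fractions`; only single-dose rows
#'   (`n_fractions == 1`, or all rows when the column is absent) are
#'   used. All `sf` must be in `(0, 1]` and at least 3 distinct positive
#'   doses are required.
#' @param weights Logical; use inverse-variance weights derived from `se`
#'   (default `FALSE`, matching an unweighted least-squares fit).
#' @return An object of class `lq_fit`: a list with `alpha` (1/Gy),
#'   `beta` (1/Gy^2), `alpha_ci`, `beta_ci` (95% intervals), `ratio`
#'   (alpha/beta, Gy; `Inf` when `beta == 0`), `r_squared`, `covariance`
#'   (2x2), `df`, `n_points`, `weighted` and `clipped`.
#' @examples
#' pts <- tibble::tibble(dose = c(0, 1, 2, 4, 6, 8, 12))
#' pts$sf <- predict_sf(0.1461, 0.08366, n = 1, d = pts$dose)
#' fit_lq(pts)
#' @export
fit_lq <- function(points, weights = FALSE) {
  points <- tibble::as_tibble(points)
  if (!"dose_per_fraction_gy" %in% names(points) && "dose" %in% names(points)) {
    points$dose_per_fraction_gy <- points$dose
  }
  if (!all(c("dose_per_fraction_gy", "sf") %in% names(points))) {
    stop("`points` needs columns `dose_per_fraction_gy` (or `dose`) and `sf`",
         call. = FALSE)
  }
  if ("n_fractions" %in% names(points)) {
    points <- points[points$n_fractions == 1, ]
  }
  if (any(points$sf <= 0 | points$sf > 1)) {
    stop("all `sf` must lie in (0, 1]", call. = FALSE)
  }
  n_distinct <- length(unique(points$dose_per_fraction_gy))
  pts <- points[points$dose_per_fraction_gy > 0, ]
  d <- pts$dose_per_fraction_gy
  if (length(unique(d)) < 2) {
    stop("singular design: need at least 2 distinct positive doses",
         call. = FALSE)
  }
  if (n_distinct < 3) {
    stop("need at least 3 points with distinct doses, got ", n_distinct,
         call. = FALSE)
  }
  y <- log(pts$sf)
  w <- NULL
  if (isTRUE(weights)) {
    if (!"se" %in% names(pts) || any(!is.finite(pts$se)) || any(pts$se <= 0)) {
      stop("weighted fit requires finite positive `se` for every point",
           call. = FALSE)
    }
    se_ln <- pts$se / pts$sf    # delta method: Var(ln sf) = (se/sf)^2
    w <- 1 / se_ln^2
  }
  dat <- data.frame(y = y, x1 = -d, x2 = -d^2)
  fit <- stats::lm(y ~ 0 + x1 + x2, data = dat, weights = w)
  est <- stats::coef(fit)
  names(est) <- c("alpha", "beta")
  # suppress summary.lm's "essentially perfect fit" warning on exact data
  covar <- suppressWarnings(stats::vcov(fit))
  dimnames(covar) <- list(c("alpha", "beta"), c("alpha", "beta"))
  df <- fit$df.residual
  se_par <- sqrt(diag(covar))
  tq <- if (df > 0) stats::qt(0.975, df) else NA_real_
  ci <- rbind(est - tq * se_par, est + tq * se_par)

  clipped <- est < 0
  if (any(clipped)) {
    warning("negative estimate(s) clipped to 0: ",
            paste(names(est)[clipped], collapse = ", "), call. = FALSE)
    est[clipped] <- 0
  }
  resid_w <- if (is.null(w)) rep(1, length(y)) else w
  ssr <- sum(resid_w * stats::residuals(fit)^2)
  r2 <- 1 - ssr / sum(resid_w * y^2)

  structure(list(
    alpha = unname(est["alpha"]),
    beta = unname(est["beta"]),
    alpha_ci = unname(ci[, "alpha"]),
    beta_ci = unname(ci[, "beta"]),
    ratio = alpha_beta_ratio(unname(est["alpha"]), unname(est["beta"])),
    r_squared = r2,
    covariance = covar,
    df = df,
    n_points = length(y),
    weighted = isTRUE(weights),
    clipped = any(clipped)
  ), class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("Linear-quadratic survival fit (ln S = -alpha d - beta d^2)\n")
  cat(sprintf("  alpha = %.4f /Gy   (95%% CI %.4f to %.4f)\n",
              x$alpha, x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf("  beta  = %.5f /Gy^2 (95%% CI %.5f to %.5f)\n",
              x$beta, x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  alpha/beta = %.2f Gy,  R^2 = %.4f  (%d points, %s)\n",
              x$ratio, x$r_squared, x$n_points,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Predict surviving fraction under the LQ model
#'
#' Assumes complete sublethal-damage repair between fractions (the assay's
#' 6 h inter-fraction interval), so an n-fraction schedule survives as the
#' single-fraction survival raised to the n-th power:
#' `S = exp(n * (-alpha * d - beta * d^2))`.
#'
#' @param alpha Linear kill coefficient, 1/Gy (`>= 0`).
#' @param beta Quadratic kill coefficient, 1/Gy^2 (`>= 0`).
#' @param n Number of fractions (integer `>= 1`).
#' @param d Dose per fraction, Gy (`>= 0`, vectorised).
#' @return Surviving fraction(s) in `(0, 1]`.
#' @examples
#' predict_sf(0.1461, 0.08366, n = 1, d = 7.19) # ~0.00462
#' @export
predict_sf <- function(alpha, beta, n = 1, d) {
  stopifnot(alpha >= 0, beta >= 0, n >= 1)
  if (any(d < 0)) stop("dose must be >= 0", call. = FALSE)
  exp(n * (-alpha * d - beta * d^2))
}

#' Invert the single-dose LQ survival curve
#'
#' Solves `beta * d^2 + alpha * d + ln(sf) = 0` for the unique
#' non-negative dose: `d = (-alpha + sqrt(alpha^2 - 4 beta ln sf)) /
#' (2 beta)` when `beta > 0` (the "+" root is the only non-negative one,
#' since the product of the roots, `ln(sf)/beta`, is negative for
#' `sf < 1`), and `d = -ln(sf) / alpha` in the pure-exponential limit
#' `beta = 0`.
#'
#' @param alpha Linear coefficient, 1/Gy.
#' @param beta Quadratic coefficient, 1/Gy^2.
#' @param sf Surviving fraction in `(0, 1]` (vectorised).
#' @return Single dose(s) in Gy giving survival `sf` on the fitted curve.
#' @export
invert_single_dose <- function(alpha, beta, sf) {
  stopifnot(alpha >= 0, beta >= 0)
  if (any(sf <= 0 | sf > 1)) {
    stop("`sf` must lie in (0, 1]", call. = FALSE)
  }
  if (alpha == 0 && beta == 0 && any(sf < 1)) {
    stop("alpha = beta = 0 admits no dose with sf < 1", call. = FALSE)
  }
  lsf <- log(sf)
  if (beta > 0) {
    (-alpha + sqrt(alpha^2 - 4 * beta * lsf)) / (2 * beta)
  } else {
    -lsf / alpha
  }
}

#' Alpha/beta ratio
#'
#' The dose (Gy) at which the linear and quadratic kill contributions are
#' equal; low for late-responding tissues such as prostate. `beta = 0`
#' yields `Inf` as an explicit pure-exponential sentinel.
#'
#' @param alpha Linear coefficient, 1/Gy (`>= 0`).
#' @param beta Quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @return The ratio alpha/beta in Gy, or `Inf` when `beta = 0`.
#' @examples
#' alpha_beta_ratio(0.1461, 0.08366) # 1.75
#' @export
alpha_beta_ratio <- function(alpha, beta) {
  stopifnot(alpha >= 0, beta >= 0)
  if (beta == 0) return(Inf)
  alpha / beta
}
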