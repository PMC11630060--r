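#' Measured equivalent single dose from a fitted survival curve
#'
#' Inverts the fitted single-dose survival curve at an observed
#' fractionated surviving fraction: the single dose whose fitted survival
#' equals the survival actually measured after the fractionated schedule.
#'
#' @param fit An `lq_fit` object (or any list with `alpha` and `beta`).
#' @param fractionated_sf Observed surviving fraction in `(0, 1]`.
#' @return Equivalent single dose in Gy.
#' @export
measured_equivalent_dose <- function(fit, fractionated_sf) {
  invert_single_dose(fit$alpha, fit$beta, fractionated_sf)
}

#' Conversion/discrepancy table
#'
#' For each source schedule and each alpha/beta ratio, computes the
#' BED-calculated equivalent single dose (or `n2`-fraction dose) and the
#' C/M percentage against the measured equivalent dose. `calculated` is
#' rounded to 2 decimal places (half away from zero), the printed-table
#' convention, and C/M is taken from the rounded value; `calculated_exact`
#' keeps full precision.
#'
#' Measured values may be given directly in Gy (`measured_gy`) or as an
#' observed fractionated surviving fraction (`measured_sf`), in which case
#' a fitted curve for that cell line must be supplied via `fits` and the
#' measured dose is obtained with [measured_equivalent_dose()].
#'
#' @param rows Tibble with columns `cell_line`, `n_fractions`,
#'   `dose_per_fraction_gy`, and `measured_gy` and/or `measured_sf`.
#' @param ratios Numeric vector of alpha/beta ratios (Gy), non-empty.
#' @param fits Named list of `lq_fit` objects keyed by cell line; only
#'   needed for rows supplying `measured_sf`.
#' @param n2 Fraction count of the target schedule (default 1: equivalent
#'   single dose).
#' @return Tibble with one row per (source row, ratio): `cell_line`,
#'   `n_fractions`, `dose_per_fraction_gy`, `ratio`, `calculated`,
#'   `calculated_exact`, `measured`, `cm`.
#' @export
conversion_table <- function(rows, ratios, fits = NULL, n2 = 1) {
  rows <- tibble::as_tibble(rows)
  if (length(ratios) == 0) stop("`ratios` must be non-empty", call. = FALSE)
  check_ratio(ratios)
  need <- c("cell_line", "n_fractions", "dose_per_fraction_gy")
  if (!all(need %in% names(rows))) {
    stop("`rows` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  measured <- rep(NA_real_, nrow(rows))
  if ("measured_gy" %in% names(rows)) measured <- rows$measured_gy
  if ("measured_sf" %in% names(rows)) {
    from_sf <- is.na(measured) & !is.na(rows$measured_sf)
    for (i in which(from_sf)) {
      fit <- fits[[rows$cell_line[i]]]
      if (is.null(fit)) {
        stop("no fit supplied for cell line '", rows$cell_line[i],
             "' (needed to convert measured_sf)", call. = FALSE)
      }
      measured[i] <- measured_equivalent_dose(fit, rows$measured_sf[i])
    }
  }
  if (any(is.na(measured))) {
    stop("every row needs `measured_gy` or `measured_sf`", call. = FALSE)
  }
  grid <- merge(cbind(rows[need], measured = measured),
                data.frame(ratio = ratios), by = NULL)
  grid <- tibble::as_tibble(grid)
  grid$calculated_exact <- equivalent_dose_per_fraction(
    grid$n_fractions, grid$dose_per_fraction_gy, n2 = n2, ratio = grid$ratio)
  grid$calculated <- round_half_away(grid$calculated_exact, 2)
  grid$cm <- cm_percent(grid$calculated, grid$measured)
  grid[order(match(grid$cell_line, rows$cell_line),
             grid$n_fractions * grid$dose_per_fraction_gy, grid$ratio),
       c("cell_line", "n_fractions", "dose_per_fraction_gy", "ratio",
         "calculated", "calculated_exact", "measured", "cm")]
}

#' BED/EQD2 schedule comparison table
#'
#' BED and EQD2 for each schedule at each of its alpha/beta ratios,
#' rounded to 1 decimal place (half away from zero) with exact values
#' alongside. Which ratio applies to which schedule is configuration: a
#' single numeric vector applies every ratio to every schedule, a list
#' gives one ratio vector per schedule (dose-dependent alpha/beta values
#' are external inputs here, not computed).
#'
#' @param schedules Tibble with columns `n_fractions`,
#'   `dose_per_fraction_gy`.
#' @param ratios Numeric vector, or list of numeric vectors with one
#'   element per schedule row.
#' @return Tibble with `n_fractions`, `dose_per_fraction_gy`, `ratio`,
#'   `bed`, `eqd2`, `bed_exact`, `eqd2_exact`.
#' @export
schedule_comparison_table <- function(schedules, ratios) {
  schedules <- tibble::as_tibble(schedules)
  if (!is.list(ratios)) {
    ratios <- rep(list(ratios), nrow(schedules))
  }
  if (length(ratios) != nrow(schedules)) {
    stop("`ratios` list must have one element per schedule", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(schedules)), function(i) {
    r <- ratios[[i]]
    check_ratio(r)
    b <- bed(schedules$n_fractions[i], schedules$dose_per_fraction_gy[i], r)
    tibble::tibble(
      n_fractions = schedules$n_fractions[i],
      dose_per_fraction_gy = schedules$dose_per_fraction_gy[i],
      ratio = r,
      bed = round_half_away(b, 1),
      eqd2 = round_half_away(eqd2(b, r), 1),
      bed_exact = b,
      eqd2_exact = eqd2(b, r)
    )
  })
  dplyr::bind_rows(rows)
}

#' C/M sensitivity to the alpha/beta ratio
#'
#' Evaluates the C/M percentage for one source schedule over a grid of
#' alpha/beta ratios. The grid must be strictly positive and ascending.
#' The returned tibble carries the attribute `ratio_reaching_100`: the
#' smallest grid ratio with `cm >= 100`, or `NA` if none.
#'
#' @param n,d Source schedule: fractions and dose per fraction (Gy).
#' @param measured_gy Measured equivalent single dose, Gy.
#' @param ratio_grid Ascending positive numeric vector of ratios (Gy).
#' @return Tibble with `ratio`, `calculated`, `calculated_exact`, `cm`.
#' @export
cm_sensitivity <- function(n, d, measured_gy, ratio_grid) {
  check_ratio(ratio_grid)
  if (is.unsorted(ratio_grid, strictly = TRUE)) {
    stop("`ratio_grid` must be strictly ascending", call. = FALSE)
  }
  calc_exact <- equivalent_dose_per_fraction(n, d, n2 = 1, ratio = ratio_grid)
  calc <- round_half_away(calc_exact, 2)
  out <- tibble::tibble(
    ratio = ratio_grid,
    calculated = calc,
    calculated_exact = calc_exact,
    cm = cm_percent(calc, measured_gy)
  )
  hit <- which(out$cm >= 100)
  attr(out, "ratio_reaching_100") <-
    if (length(hit) > 0) ratio_grid[hit[1]] else NA_real_
  out
}

#' Write a results table as CSV and JSON
#'
#' Writes `<path>.csv` and `<path>.json`. The JSON rendering keeps full
#' numeric precision, so exact (unrounded) columns survive a round trip.
#'
#' @param rows Non-empty tibble (e.g. from [conversion_table()]).
#' @param path Output path without extension.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) stop("`rows` must be non-empty", call. = FALSE)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(rows, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(rows, json, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' Read back a JSON report
#'
#' @param path Path to a `.json` file written by [write_report()].
#' @return Tibble.
#' @export
read_report_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
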