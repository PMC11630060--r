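#' Plating efficiency
#'
#' Fraction of seeded cells that form a colony (>= 50 cells). Stored as a
#' fraction in `[0, 1]`; multiply by 100 for the conventional percentage
#' display.
#'
#' @param colonies Number of colonies counted (non-negative integer,
#'   vectorised).
#' @param seeded Number of cells seeded (positive integer, vectorised).
#' @return Numeric vector of plating efficiencies in `[0, 1]`.
#' @examples
#' plating_efficiency(50, 500) # 0.1
#' @export
plating_efficiency <- function(colonies, seeded) {
  if (any(!is.finite(seeded)) || any(seeded <= 0)) {
    stop("`seeded` must be a positive count", call. = FALSE)
  }
  if (any(!is.finite(colonies)) || any(colonies < 0)) {
    stop("`colonies` must be a non-negative count", call. = FALSE)
  }
  if (any(colonies > seeded)) {
    stop("`colonies` cannot exceed `seeded`", call. = FALSE)
  }
  colonies / seeded
}

#' Surviving fraction
#'
#' Plating efficiency of an irradiated group divided by that of the
#' unirradiated control. Values above 1 can arise from sampling noise and
#' are kept, with a warning. A surviving fraction of exactly 0 is returned
#' as-is; downstream log-domain fitting excludes such points.
#'
#' @param pe_irradiated Plating efficiency of the irradiated group
#'   (fraction, vectorised).
#' @param pe_control Plating efficiency of the control group (fraction,
#'   `> 0`, vectorised).
#' @return Numeric vector of surviving fractions.
#' @examples
#' surviving_fraction(0.05, 0.10) # 0.5
#' @export
surviving_fraction <- function(pe_irradiated, pe_control) {
  if (any(!is.finite(pe_control)) || any(pe_control <= 0)) {
    stop("`pe_control` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(pe_irradiated)) || any(pe_irradiated < 0)) {
    stop("`pe_irradiated` must be >= 0", call. = FALSE)
  }
  sf <- pe_irradiated / pe_control
  if (any(sf > 1)) {
    warning("surviving fraction > 1 (sampling noise); value kept",
            call. = FALSE)
  }
  sf
}

assay_columns <- c("cell_line", "n_fractions", "dose_per_fraction_gy",
                   "cells_seeded", "colonies", "replicate")

validate_assay_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(assay_columns, names(records))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("n_fractions", "dose_per_fraction_gy", "cells_seeded",
                "colonies")) {
    v <- records[[col]]
    if (is.character(v)) {
      suppressWarnings(v <- as.numeric(v))
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric or missing `", col, "` on row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    records[[col]] <- v
  }
  checks <- list(
    "n_fractions must be an integer >= 1" =
      records$n_fractions >= 1 & records$n_fractions == round(records$n_fractions),
    "dose_per_fraction_gy must be >= 0" = records$dose_per_fraction_gy >= 0,
    "cells_seeded must be > 0" = records$cells_seeded > 0,
    "colonies must be >= 0" = records$colonies >= 0,
    "colonies cannot exceed cells_seeded" =
      records$colonies <= records$cells_seeded
  )
  for (msg in names(checks)) {
    bad <- which(!checks[[msg]])
    if (length(bad) > 0) {
      stop(msg, " (row(s) ", paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  records$cell_line <- as.character(records$cell_line)
  records$replicate <- as.character(records$replicate)
  records[assay_columns]
}

#' Read a clonogenic-assay table from CSV
#'
#' Expects a comma-separated, UTF-8, dot-decimal file with a header row
#' naming the columns `cell_line`, `n_fractions`, `dose_per_fraction_gy`,
#' `cells_seeded`, `colonies`, `replicate`. Every row is validated
#' (positive seeding, colonies not exceeding seeded cells, integer
#' fraction counts); offending rows are reported by number.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated assay records, one row per well.
#' @seealso [write_assay_table()], [aggregate_replicates()]
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    warning("assay table is empty: ", path, call. = FALSE)
    return(tibble::tibble(cell_line = character(), n_fractions = numeric(),
                          dose_per_fraction_gy = numeric(),
                          cells_seeded = numeric(), colonies = numeric(),
                          replicate = character()))
  }
  validate_assay_records(raw)
}

#' Write a clonogenic-assay table to CSV
#'
#' @param records Tibble of assay records as returned by
#'   [read_assay_table()] or [simulate_assay()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(records, path) {
  records <- validate_assay_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate replicate wells into survival points
#'
#' Per cell line and schedule, computes the plating efficiency of each
#' replicate, divides it by the same replicate's unirradiated control PE
#' (falling back to the pooled control PE if that replicate has no
#' control well), and summarises across replicates as mean surviving
#' fraction with standard error `sd / sqrt(k)`. Schedules whose mean
#' surviving fraction is exactly 0 (no colonies in any replicate) cannot
#' enter a log-domain fit and are dropped with a warning. The zero-dose
#' control is reported with `sf = 1` and `se = NA` (it is 1 by
#' construction).
#'
#' @param records Tibble of assay records; must contain at least one
#'   zero-dose control group per cell line.
#' @return Tibble with columns `cell_line`, `n_fractions`,
#'   `dose_per_fraction_gy`, `sf`, `se`, `n_replicates`. `se` is `NA` for
#'   single-replicate schedules.
#' @export
aggregate_replicates <- function(records) {
  records <- validate_assay_records(records)
  records$total_dose <- records$n_fractions * records$dose_per_fraction_gy
  records$pe <- plating_efficiency(records$colonies, records$cells_seeded)

  out <- lapply(split(records, records$cell_line), function(cl) {
    ctrl <- cl[cl$total_dose == 0, ]
    if (nrow(ctrl) == 0) {
      stop("no unirradiated control group for cell line '",
           cl$cell_line[1], "'", call. = FALSE)
    }
    if (any(ctrl$colonies == 0)) {
      stop("control well with zero colonies for cell line '",
           cl$cell_line[1], "' (plating efficiency undefined)",
           call. = FALSE)
    }
    # same-replicate control PE, pooled fallback
    ctrl_pe <- vapply(split(ctrl$pe, ctrl$replicate), mean, numeric(1))
    pooled_pe <- sum(ctrl$colonies) / sum(ctrl$cells_seeded)
    cl$pe_ctrl <- ifelse(cl$replicate %in% names(ctrl_pe),
                         unname(ctrl_pe[cl$replicate]), pooled_pe)
    cl$sf_rep <- suppressWarnings(surviving_fraction(cl$pe, cl$pe_ctrl))
    cl |>
      dplyr::group_by(.data$cell_line, .data$n_fractions,
                      .data$dose_per_fraction_gy) |>
      dplyr::summarise(
        sf = mean(.data$sf_rep),
        se = if (dplyr::n() > 1) stats::sd(.data$sf_rep) / sqrt(dplyr::n())
             else NA_real_,
        n_replicates = dplyr::n(),
        .groups = "drop"
      )
  })
  out <- dplyr::bind_rows(out)
  is_ctrl <- out$n_fractions * out$dose_per_fraction_gy == 0
  out$sf[is_ctrl] <- 1
  out$se[is_ctrl] <- NA_real_
  zero <- !is_ctrl & out$sf == 0
  if (any(zero)) {
    warning(sum(zero), " schedule(s) with surviving fraction 0 excluded ",
            "(log-survival undefined)", call. = FALSE)
    out <- out[!zero, ]
  }
  out <- out[order(out$cell_line, out$n_fractions * out$dose_per_fraction_gy,
                   out$n_fractions), ]
  tibble::as_tibble(out)
}

#' Write aggregated survival points to CSV
#'
#' @param points Tibble from [aggregate_replicates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
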