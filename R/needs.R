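#' Construct a needs table
#'
#' A needs table lists health conditions with a per-capita annual rate
#' (incidence or prevalence, treated identically as a point-in-time per-capita
#' rate) and a planned level of service (items dispensed per affected person
#' per year). Rates may be stratified by age band and sex; `"all"` in either
#' column applies the row to every age and/or sex.
#'
#' @param rows A data frame with columns `condition`, `age_band`, `sex`,
#'   `rate` (fraction in \[0, 1\]) and `items_per_person_per_year`
#'   (non-negative). `age_band`/`sex` default to `"all"` when absent.
#' @return A tibble of class `hrh_needs`.
#' @examples
#' needs <- hrh_needs(tibble::tibble(
#'   condition = "hypertension", rate = 0.25, items_per_person_per_year = 6))
#' pop <- hrh_population(1000)
#' required_services(pop, needs, share = 1)
#' @export
hrh_needs <- function(rows) {
  rows <- as_tibble(rows)
  if (!"age_band" %in% names(rows)) rows$age_band <- "all"
  if (!"sex" %in% names(rows)) rows$sex <- "all"
  required <- c("condition", "age_band", "sex", "rate",
                "items_per_person_per_year")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0L) {
    abort(paste0("Needs table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  rows <- rows[required]
  rows$condition <- as.character(rows$condition)
  rows$age_band <- as.character(rows$age_band)
  rows$sex <- as.character(rows$sex)
  rows$rate <- as.numeric(rows$rate)
  rows$items_per_person_per_year <- as.numeric(rows$items_per_person_per_year)
  if (anyNA(rows$rate) || any(rows$rate < 0 | rows$rate > 1)) {
    abort("Needs rates must lie in [0, 1].")
  }
  if (anyNA(rows$items_per_person_per_year) ||
      any(rows$items_per_person_per_year < 0)) {
    abort("items_per_person_per_year must be non-negative.")
  }
  if (anyDuplicated(rows[c("condition", "age_band", "sex")]) > 0L) {
    abort("Duplicated (condition, age_band, sex) rows in needs table.")
  }
  structure(rows, class = c("hrh_needs", class(tibble())))
}

# Persons a needs row applies to; errors when the row names a stratum the
# population does not carry.
needs_row_population <- function(pop, age_band, sex, condition) {
  sel <- rep(TRUE, nrow(pop))
  if (age_band != "all") sel <- sel & pop$age_band == age_band
  if (sex != "all") sel <- sel & pop$sex == sex
  if (age_band != "all" || sex != "all") {
    if (!any(sel)) {
      abort(sprintf(
        paste0("Stratification mismatch: needs row for condition '%s' refers ",
               "to stratum (age_band = '%s', sex = '%s') absent from the ",
               "population table."),
        condition, age_band, sex), class = "hrh_stratification_error")
    }
  }
  sum(pop$count[sel])
}

#' Annual services required by a population
#'
#' Computes the needs-based service requirement: for each condition and
#' stratum, persons x rate x level of service, summed over the table, then
#' multiplied by the share of services the modelled (public) sector is
#' responsible for. The result is linear in the population, in every rate and
#' level of service, and in the share. The share is applied here and only
#' here; [required_fte()] assumes it has already been applied.
#'
#' @param pop An [hrh_population()].
#' @param needs An [hrh_needs()] table.
#' @param share Fraction of required services attributed to the modelled
#'   sector, in \[0, 1\].
#' @return Required services (items/year), a single non-negative number.
#' @export
required_services <- function(pop, needs, share) {
  stopifnot(inherits(pop, "hrh_population"), inherits(needs, "hrh_needs"))
  check_fraction(share, "share")
  if (nrow(pop) == 0L || total_population(pop) == 0) return(0)
  per_row <- purrr::pmap_dbl(
    list(needs$age_band, needs$sex, needs$condition,
         needs$rate, needs$items_per_person_per_year),
    function(band, sex, cond, rate, items) {
      needs_row_population(pop, band, sex, cond) * rate * items
    })
  share * sum(per_row)
}

#' Convert a service requirement to required FTE providers
#'
#' Divides the annual number of required services by productivity (annual
#' items dispensed per full-time-equivalent provider). `items` must already
#' reflect any sector share — the share is applied exactly once, in
#' [required_services()].
#'
#' @param items Required services per year (non-negative).
#' @param productivity Items dispensed per FTE per year (strictly positive).
#' @return Required FTE, a single non-negative number.
#' @export
required_fte <- function(items, productivity) {
  check_number(items, "items", lower = 0)
  check_number(productivity, "productivity")
  if (productivity <= 0) abort("`productivity` must be strictly positive.")
  items / productivity
}

#' Read or write a needs table as CSV
#'
#' Columns: `condition`, `age_band`, `sex`, `rate`,
#' `items_per_person_per_year`; `"all"` is permitted in `age_band` and `sex`.
#'
#' @param path File path.
#' @return `read_needs_csv()` returns an `hrh_needs` tibble;
#'   `write_needs_csv()` returns `path` invisibly.
#' @export
read_needs_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    age_band = readr::col_character(),
    sex = readr::col_character(),
    rate = readr::col_double(),
    items_per_person_per_year = readr::col_double()
  ))
  hrh_needs(df)
}

#' @param needs An [hrh_needs()] table.
#' @rdname read_needs_csv
#' @export
write_needs_csv <- function(needs, path) {
  readr::write_csv(tibble::as_tibble(needs), path)
  invisible(path)
}
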