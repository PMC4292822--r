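#' Provider stock by single year of age
#'
#' The supply state: a headcount of licensed providers for every single year
#' of age between `min_age` and `max_age`. Tracking single-year ages lets the
#' stock "age" through the exit schedule, which is what makes the age
#' distribution a powerful short-run determinant of supply growth or decline.
#'
#' @param counts A data frame with integer `age` and non-negative `headcount`
#'   columns (ages absent from the table hold zero), or a single total to be
#'   placed with [triangular_age_counts()].
#' @param year Integer calendar (or simulation) year of the state.
#' @param min_age,max_age Inclusive age bounds; `max_age` is absorbing.
#' @return A tibble of class `hrh_stock` with one row per age in
#'   `[min_age, max_age]` and attributes `year`, `min_age`, `max_age`.
#' @export
provider_stock <- function(counts, year = 0L, min_age = 23L, max_age = 75L) {
  min_age <- check_count(min_age, "min_age")
  max_age <- check_count(max_age, "max_age")
  if (max_age < min_age) abort("`max_age` must be >= `min_age`.")
  ages <- min_age:max_age
  headcount <- rep(0, length(ages))
  counts <- as_tibble(counts)
  if (nrow(counts) > 0L) {
    if (!all(c("age", "headcount") %in% names(counts))) {
      abort("Stock table needs columns `age` and `headcount`.")
    }
    if (anyNA(counts$headcount) || any(counts$headcount < 0)) {
      abort("Stock headcounts must be non-negative.")
    }
    if (any(counts$age < min_age | counts$age > max_age)) {
      abort("Stock ages fall outside [min_age, max_age].")
    }
    idx <- match(as.integer(counts$age), ages)
    headcount[idx] <- headcount[idx] + as.numeric(counts$headcount)
  }
  structure(tibble(age = ages, headcount = headcount),
            class = c("hrh_stock", class(tibble())),
            year = as.integer(year), min_age = min_age, max_age = max_age)
}

#' @export
print.hrh_stock <- function(x, ...) {
  cat(sprintf("<hrh_stock> year %d, total %.2f providers, ages %d-%d\n",
              attr(x, "year"), stock_total(x),
              attr(x, "min_age"), attr(x, "max_age")))
  NextMethod()
}

#' Total headcount of a provider stock
#' @param stock An [provider_stock()].
#' @return A single non-negative number.
#' @export
stock_total <- function(stock) sum(stock$headcount)

#' Discretized triangular age distribution
#'
#' Weights proportional to `max_age - age + 1` over `[min_age, max_age]`: a
#' decreasing triangle whose discrete mean over ages 23-62 is exactly 36,
#' matching an observed stock reported only as a headcount with mean age 36.
#' Flat-exit projections are insensitive to the within-stock age placement,
#' so any distribution with the right mean serves; this one is simple and
#' regenerable.
#'
#' @param total Total headcount to distribute.
#' @param min_age,max_age Inclusive bounds of the triangle.
#' @return A tibble with columns `age` and `headcount` summing to `total`.
#' @export
triangular_age_counts <- function(total, min_age = 23L, max_age = 62L) {
  check_number(total, "total", lower = 0)
  ages <- min_age:max_age
  w <- (max_age - ages + 1)
  tibble(age = ages, headcount = total * w / sum(w))
}

#' Age-indexed annual exit schedule
#'
#' Annual probability of leaving the regional stock (retirement, relocation
#' and death combined) by single year of age. A flat rate is the degenerate
#' schedule. The rate at `max_age` doubles as the terminal rate applied to
#' the absorbing top age.
#'
#' @param rates A data frame with columns `age` and `exit_rate`, or a single
#'   flat rate in \[0, 1\].
#' @param min_age,max_age Age range the schedule must cover.
#' @return A tibble of class `hrh_exits` with one row per age.
#' @export
exit_schedule <- function(rates, min_age = 23L, max_age = 75L) {
  ages <- min_age:max_age
  if (is.numeric(rates) && length(rates) == 1L) {
    check_fraction(rates, "exit rate")
    df <- tibble(age = ages, exit_rate = rates)
  } else {
    df <- as_tibble(rates)
    if (!all(c("age", "exit_rate") %in% names(df))) {
      abort("Exit schedule needs columns `age` and `exit_rate`.")
    }
    idx <- match(ages, as.integer(df$age))
    if (anyNA(idx)) {
      abort("Exit schedule must cover every age in [min_age, max_age].")
    }
    df <- tibble(age = ages, exit_rate = as.numeric(df$exit_rate[idx]))
  }
  if (anyNA(df$exit_rate) || any(df$exit_rate < 0 | df$exit_rate > 1)) {
    abort("Exit rates must lie in [0, 1].")
  }
  structure(df, class = c("hrh_exits", class(tibble())))
}

#' Scale exit rates above an age cut-off
#'
#' Multiplies exit rates at ages `>= age_from` by `multiplier` (capped at 1),
#' the hook used to rehearse alternative retirement scenarios.
#'
#' @param exits An [exit_schedule()].
#' @param age_from First age affected.
#' @param multiplier Non-negative multiplier.
#' @return The adjusted `hrh_exits` schedule.
#' @export
adjust_exit_schedule <- function(exits, age_from, multiplier) {
  stopifnot(inherits(exits, "hrh_exits"))
  check_number(multiplier, "multiplier", lower = 0)
  sel <- exits$age >= age_from
  exits$exit_rate[sel] <- pmin(1, exits$exit_rate[sel] * multiplier)
  exits
}

#' Annual inflows to the provider stock
#'
#' @param entrants_per_year New graduates entering the stock this year
#'   (already net of training attrition and out-migration).
#' @param in_migration_per_year Providers arriving from other regions or
#'   countries.
#' @param entrant_age_distribution A data frame with columns `age` and
#'   `weight` summing to 1, or a single age for a point mass. In-migrants
#'   share the entrant distribution.
#' @return A list of class `hrh_flows`.
#' @export
supply_flows <- function(entrants_per_year, in_migration_per_year = 0,
                         entrant_age_distribution = 23L) {
  check_number(entrants_per_year, "entrants_per_year", lower = 0)
  check_number(in_migration_per_year, "in_migration_per_year", lower = 0)
  d <- entrant_age_distribution
  if (is.numeric(d) && length(d) == 1L) {
    d <- tibble(age = as.integer(d), weight = 1)
  } else {
    d <- as_tibble(d)[c("age", "weight")]
    if (abs(sum(d$weight) - 1) > 1e-9 || any(d$weight < 0)) {
      abort("Entrant age weights must be non-negative and sum to 1.")
    }
  }
  structure(list(entrants_per_year = entrants_per_year,
                 in_migration_per_year = in_migration_per_year,
                 entrant_age_distribution = d),
            class = "hrh_flows")
}

#' Advance the provider stock by one year
#'
#' Within-year event order is fixed: exits are applied to the start-of-year
#' stock, survivors age by one year (the top age is absorbing), then entrants
#' and in-migrants are added at the entrant age distribution. Headcount is
#' conserved exactly: total out = total in - exits + entrants + in-migrants.
#'
#' @param stock An [provider_stock()].
#' @param flows An [supply_flows()] for the year.
#' @param exits An [exit_schedule()] covering the stock's age range.
#' @return The next year's `hrh_stock`.
#' @export
step_supply <- function(stock, flows, exits) {
  stopifnot(inherits(stock, "hrh_stock"), inherits(flows, "hrh_flows"),
            inherits(exits, "hrh_exits"))
  ages <- stock$age
  rates <- exits$exit_rate[match(ages, exits$age)]
  if (anyNA(rates)) abort("Exit schedule does not cover the stock's ages.")
  survivors <- stock$headcount * (1 - rates)
  n <- length(ages)
  aged <- c(0, survivors[-n])
  aged[n] <- aged[n] + survivors[n]  # absorbing top age
  inflow_total <- flows$entrants_per_year + flows$in_migration_per_year
  d <- flows$entrant_age_distribution
  idx <- match(as.integer(d$age), ages)
  if (anyNA(idx)) abort("Entrant ages fall outside the stock's age range.")
  aged[idx] <- aged[idx] + inflow_total * d$weight
  out <- stock
  out$headcount <- aged
  attr(out, "year") <- attr(stock, "year") + 1L
  out
}

#' Project the provider stock over a horizon
#'
#' Iterates [step_supply()]. Flows may be constant or vary by year (as when
#' entrants are driven by the training pipeline).
#'
#' @param stock Initial [provider_stock()].
#' @param flows An [supply_flows()] applied every year, or a list of
#'   `horizon` flow objects, one per step.
#' @param exits An [exit_schedule()].
#' @param horizon Non-negative integer number of annual steps.
#' @return A list of `horizon + 1` stocks, element 1 the initial state.
#' @export
project_supply <- function(stock, flows, exits, horizon) {
  horizon <- check_count(horizon, "horizon", lower = 0)
  if (inherits(flows, "hrh_flows")) flows <- rep(list(flows), horizon)
  if (length(flows) != horizon) {
    abort("`flows` must supply one flow object per projection step.")
  }
  out <- vector("list", horizon + 1L)
  out[[1L]] <- stock
  for (t in seq_len(horizon)) {
    stock <- step_supply(stock, flows[[t]], exits)
    out[[t + 1L]] <- stock
  }
  out
}

#' Closed-form stock total under a flat exit rate and constant inflow
#'
#' Independent oracle for the flat-rate special case: with exit rate `e` and
#' constant annual inflow `G`, the total after `t` years is the geometric sum
#' `n0 (1-e)^t + G (1 - (1-e)^t) / e` (and `n0 + G t` when `e = 0`). Because
#' a flat rate removes the same fraction at every age, the age structure is
#' irrelevant to the total and the full cohort projection must agree with
#' this formula.
#'
#' @param n0 Initial total headcount (non-negative).
#' @param flat_exit Annual exit rate in \[0, 1\].
#' @param entrants Constant annual inflow (non-negative).
#' @param t Non-negative integer years.
#' @return The projected total headcount.
#' @export
closed_form_supply <- function(n0, flat_exit, entrants, t) {
  check_number(n0, "n0", lower = 0)
  check_fraction(flat_exit, "flat_exit")
  check_number(entrants, "entrants", lower = 0)
  t <- check_count(t, "t", lower = 0)
  s <- (1 - flat_exit)^t
  if (flat_exit == 0) n0 + entrants * t else n0 * s + entrants * (1 - s) / flat_exit
}

#' Read or write a provider stock as CSV (columns `age`, `headcount`)
#' @param path File path.
#' @param year,min_age,max_age Passed to [provider_stock()] on read.
#' @return `read_stock_csv()` returns an `hrh_stock`; `write_stock_csv()`
#'   returns `path` invisibly.
#' @export
read_stock_csv <- function(path, year = 0L, min_age = 23L, max_age = 75L) {
  df <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), headcount = readr::col_double()))
  provider_stock(df, year = year, min_age = min_age, max_age = max_age)
}

#' @param stock An [provider_stock()].
#' @rdname read_stock_csv
#' @export
write_stock_csv <- function(stock, path) {
  readr::write_csv(tibble::as_tibble(stock)[c("age", "headcount")], path)
  invisible(path)
}
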