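#' Participation, activity and productivity rates
#'
#' Converts the licensed headcount into public-sector full-time-equivalent
#' (FTE) capacity. Participation is the share of the regional stock employed
#' in the public sector; activity is the share of one FTE the average
#' participant works, with values above 1 representing overtime "sessions"
#' (for example 50 h worked against a 40 h nominal week is an activity of
#' 1.25). Productivity (annual items dispensed per FTE) and its optional
#' annual growth rate live here too.
#'
#' @param participation_rate Fraction of the stock employed in the modelled
#'   sector, in \[0, 1\].
#' @param activity_rate Share of one FTE the average participant works,
#'   strictly positive; values above `activity_cap` trigger a warning.
#' @param fte_hours_per_week Nominal full-time hours per week (default 40).
#' @param productivity_growth_rate Annual compounded growth in productivity
#'   (fraction/yr, default 0, must exceed -1).
#' @param activity_cap Largest plausible sustained activity (default 1.5).
#' @return A list of class `hrh_rates`.
#' @export
workforce_rates <- function(participation_rate = 1,
                            activity_rate = 1,
                            fte_hours_per_week = 40,
                            productivity_growth_rate = 0,
                            activity_cap = 1.5) {
  check_fraction(participation_rate, "participation_rate")
  check_number(activity_rate, "activity_rate")
  if (activity_rate <= 0) abort("`activity_rate` must be strictly positive.")
  check_number(fte_hours_per_week, "fte_hours_per_week")
  if (fte_hours_per_week <= 0) abort("`fte_hours_per_week` must be positive.")
  check_number(productivity_growth_rate, "productivity_growth_rate")
  if (productivity_growth_rate <= -1) {
    abort("`productivity_growth_rate` must be greater than -1.")
  }
  check_number(activity_cap, "activity_cap")
  if (activity_rate > activity_cap) {
    warn(sprintf(
      "activity_rate %.3g exceeds the activity cap %.3g; treating as sustained overtime.",
      activity_rate, activity_cap))
  }
  structure(list(participation_rate = participation_rate,
                 activity_rate = activity_rate,
                 fte_hours_per_week = fte_hours_per_week,
                 productivity_growth_rate = productivity_growth_rate,
                 activity_cap = activity_cap),
            class = "hrh_rates")
}

#' Public-sector FTE supply from a headcount
#'
#' `headcount x participation x activity`. Forcing `activity = 1` gives the
#' "no-sessions" capacity — what the employed stock could deliver without
#' overtime — which never exceeds the with-sessions figure when activity is
#' above 1.
#'
#' @param stock_total Licensed headcount (non-negative).
#' @param rates An [workforce_rates()] object.
#' @param activity Optional activity override (used for the no-sessions
#'   column); defaults to `rates$activity_rate`.
#' @return FTE supply, a single non-negative number.
#' @export
fte_supply <- function(stock_total, rates, activity = rates$activity_rate) {
  stopifnot(inherits(rates, "hrh_rates"))
  check_number(stock_total, "stock_total", lower = 0)
  stock_total * rates$participation_rate * activity
}

#' Activity rate implied by weekly hours
#'
#' @param hours_per_week Average weekly hours actually worked (positive).
#' @param fte_hours Nominal full-time weekly hours (positive, default 40).
#' @return `hours_per_week / fte_hours`.
#' @export
activity_from_hours <- function(hours_per_week, fte_hours = 40) {
  check_number(hours_per_week, "hours_per_week")
  check_number(fte_hours, "fte_hours")
  if (hours_per_week <= 0 || fte_hours <= 0) {
    abort("Hours must be strictly positive.")
  }
  hours_per_week / fte_hours
}

#' Productivity after compounded annual growth
#'
#' @param base Items per FTE per year at the reference year (positive).
#' @param growth Annual growth rate (fraction/yr, must exceed -1).
#' @param year_offset Non-negative integer years beyond the reference year.
#' @return `base * (1 + growth)^year_offset`.
#' @export
productivity_at <- function(base, growth, year_offset) {
  check_number(base, "base")
  if (base <= 0) abort("`base` productivity must be positive.")
  check_number(growth, "growth")
  if (growth <= -1) abort("`growth` must be greater than -1.")
  year_offset <- check_count(year_offset, "year_offset", lower = 0)
  base * (1 + growth)^year_offset
}

#' Productivity implied by observed output and FTE
#'
#' @param items_dispensed Annual items dispensed (non-negative).
#' @param fte FTE that dispensed them (strictly positive).
#' @return Items per FTE per year.
#' @export
implied_productivity <- function(items_dispensed, fte) {
  check_number(items_dispensed, "items_dispensed", lower = 0)
  check_number(fte, "fte")
  if (fte <= 0) abort("`fte` must be strictly positive.")
  items_dispensed / fte
}
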