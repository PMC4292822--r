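#' Training-programme parameters
#'
#' Describes the single national training programme feeding the regional
#' supply: annual first-year intake (seats), programme length, total
#' programme attrition, and the fraction of graduates who never enter the
#' modelled regional supply (graduate out-migration).
#'
#' Attrition is applied once, as a survival factor at graduation, so a cohort
#' of `S` entrants yields `S * (1 - attrition_rate)` graduates after
#' `programme_length` years; with 85 seats and 18% attrition this reproduces
#' the roughly 70 graduates per year the baseline data report.
#'
#' @param seats_per_year Non-negative intake of first-year students.
#' @param programme_length_years Positive integer years from entry to
#'   graduation (a point mass; the engine advances whole-year cohorts).
#' @param attrition_rate Fraction of entrants who never graduate, in \[0, 1\].
#' @param graduate_outmigration_rate Fraction of graduates who do not enter
#'   the modelled regional supply, in \[0, 1\].
#' @return A list of class `hrh_training_params`.
#' @export
training_params <- function(seats_per_year = 85,
                            programme_length_years = 4L,
                            attrition_rate = 0.18,
                            graduate_outmigration_rate = 0.90) {
  check_number(seats_per_year, "seats_per_year", lower = 0)
  programme_length_years <- check_count(programme_length_years,
                                        "programme_length_years", lower = 1)
  check_fraction(attrition_rate, "attrition_rate")
  check_fraction(graduate_outmigration_rate, "graduate_outmigration_rate")
  structure(list(seats_per_year = seats_per_year,
                 programme_length_years = programme_length_years,
                 attrition_rate = attrition_rate,
                 graduate_outmigration_rate = graduate_outmigration_rate),
            class = "hrh_training_params")
}

#' In-training cohorts indexed by years remaining to graduation
#'
#' The pipeline state is a non-negative numeric vector `cohorts` whose `p`-th
#' element is the number of students who will graduate after `p` more annual
#' advances. Fractional students are carried exactly; rounding happens only in
#' reports.
#'
#' @param cohorts Numeric vector of length `programme_length_years`, position
#'   1 = graduating at the next advance.
#' @return A list of class `hrh_pipeline`.
#' @export
training_pipeline <- function(cohorts) {
  cohorts <- as.numeric(cohorts)
  if (length(cohorts) < 1L || anyNA(cohorts) || any(cohorts < 0)) {
    abort("Pipeline cohorts must be a non-empty non-negative numeric vector.")
  }
  structure(list(cohorts = cohorts), class = "hrh_pipeline")
}

#' Pipeline at steady state for a constant intake
#'
#' Every cohort position holds one full year's intake, so the pipeline
#' immediately produces the steady-state graduate flow
#' `seats * (1 - attrition)`.
#'
#' @param params An [training_params()] object.
#' @param intakes Optional numeric vector of historical intakes, oldest
#'   (graduating next) first; defaults to `seats_per_year` repeated.
#' @return An `hrh_pipeline`.
#' @export
steady_state_pipeline <- function(params, intakes = NULL) {
  stopifnot(inherits(params, "hrh_training_params"))
  L <- params$programme_length_years
  if (is.null(intakes)) intakes <- rep(params$seats_per_year, L)
  if (length(intakes) != L) {
    abort("`intakes` must have one entry per programme year.")
  }
  training_pipeline(intakes)
}

#' Advance the training pipeline by one year
#'
#' The cohort one year from graduation graduates (with the survival factor
#' `1 - attrition_rate` applied), every other cohort moves one year closer,
#' and a new intake enters at the full programme length.
#'
#' @param pipeline An [training_pipeline()] state.
#' @param params An [training_params()] object.
#' @param intake Intake entering this year; defaults to
#'   `params$seats_per_year`.
#' @return A list with elements `pipeline` (the advanced state) and
#'   `graduates` (this year's graduate flow, non-negative real).
#' @export
advance_pipeline <- function(pipeline, params, intake = params$seats_per_year) {
  stopifnot(inherits(pipeline, "hrh_pipeline"),
            inherits(params, "hrh_training_params"))
  check_number(intake, "intake", lower = 0)
  cohorts <- pipeline$cohorts
  if (length(cohorts) != params$programme_length_years) {
    abort("Pipeline length does not match the programme length.")
  }
  graduates <- cohorts[1L] * (1 - params$attrition_rate)
  cohorts <- c(cohorts[-1L], intake)
  list(pipeline = training_pipeline(cohorts), graduates = graduates)
}

#' Graduates entering the modelled regional supply
#'
#' Applies graduate out-migration: only `1 - graduate_outmigration_rate` of a
#' year's graduates enter the regional stock.
#'
#' @param graduates Non-negative graduate flow.
#' @param params An [training_params()] object.
#' @return Entrants per year, a non-negative number.
#' @export
entrants_to_supply <- function(graduates, params) {
  stopifnot(inherits(params, "hrh_training_params"))
  check_number(graduates, "graduates", lower = 0)
  graduates * (1 - params$graduate_outmigration_rate)
}

#' First year a seat change shows up in the graduate flow
#'
#' A change in first-year intake at `change_year` cannot alter the graduate
#' flow before the changed cohort has completed the programme, so the first
#' affected year is `change_year + programme_length_years`. This is the lag
#' that makes enrolment increases a slow policy lever.
#'
#' @param baseline,changed [training_params()] objects differing only in
#'   `seats_per_year`.
#' @param change_year Integer year the new intake first applies.
#' @return Integer year the graduate flow first differs, or `NA_integer_`
#'   when the parameters are identical (the flow never differs).
#' @export
seat_change_lag <- function(baseline, changed, change_year) {
  stopifnot(inherits(baseline, "hrh_training_params"),
            inherits(changed, "hrh_training_params"))
  other <- c("programme_length_years", "attrition_rate",
             "graduate_outmigration_rate")
  if (!identical(baseline[other], changed[other])) {
    abort("`baseline` and `changed` may differ only in seats_per_year.")
  }
  if (baseline$seats_per_year == changed$seats_per_year) return(NA_integer_)
  as.integer(change_year + baseline$programme_length_years)
}
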