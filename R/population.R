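#' Construct a stratified population structure
#'
#' A population structure is a tibble of person-counts by age band and sex,
#' together with a reference year and an annual growth rate. A single
#' `age_band = "all"`, `sex = "all"` row is a legal degenerate structure and is
#' how aggregate-only data (for example a regional total of 1.33 million) is
#' represented.
#'
#' @param counts A data frame with columns `age_band` (character), `sex`
#'   (character) and `count` (non-negative person-counts). A single number is
#'   shorthand for one all-ages/all-sexes stratum.
#' @param reference_year Integer calendar year the counts describe.
#' @param growth_rate Annual population growth rate as a fraction (may be 0 or
#'   negative, but must exceed -1). Growth is applied multiplicatively and
#'   uniformly across strata by [project_population()].
#' @return A tibble of class `hrh_population` with columns `age_band`, `sex`,
#'   `count` and attributes `reference_year` and `growth_rate`.
#' @examples
#' pop <- hrh_population(1330000, reference_year = 2008, growth_rate = 0.01)
#' project_population(pop, 1)
#' @export
hrh_population <- function(counts, reference_year = 0L, growth_rate = 0) {
  if (is.numeric(counts) && length(counts) == 1L) {
    counts <- tibble(age_band = "all", sex = "all", count = as.numeric(counts))
  }
  counts <- as_tibble(counts)
  required <- c("age_band", "sex", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0L) {
    abort(paste0("Population table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  counts <- counts[required]
  counts$age_band <- as.character(counts$age_band)
  counts$sex <- as.character(counts$sex)
  counts$count <- as.numeric(counts$count)
  if (anyNA(counts$count) || any(counts$count < 0)) {
    abort("Population counts must be non-negative and non-missing.")
  }
  if (anyDuplicated(counts[c("age_band", "sex")]) > 0L) {
    abort("Duplicated (age_band, sex) strata in population table.")
  }
  check_number(growth_rate, "growth_rate")
  if (growth_rate <= -1) {
    abort("`growth_rate` must be greater than -1.")
  }
  structure(counts,
            class = c("hrh_population", class(tibble())),
            reference_year = as.integer(reference_year),
            growth_rate = growth_rate)
}

#' @export
print.hrh_population <- function(x, ...) {
  cat(sprintf("<hrh_population> total %s persons, reference year %d, growth %.4g/yr\n",
              format(round(total_population(x)), big.mark = ","),
              attr(x, "reference_year"), attr(x, "growth_rate")))
  NextMethod()
}

#' Total person-count of a population structure
#' @param pop An [hrh_population()].
#' @return A single non-negative number.
#' @export
total_population <- function(pop) sum(pop$count)

#' Project a population forward under uniform growth
#'
#' Scales every stratum by `(1 + growth_rate)^year_offset`, preserving the
#' age/sex proportions exactly; a zero growth rate is the identity.
#'
#' @param pop An [hrh_population()].
#' @param year_offset Non-negative integer number of years beyond the
#'   reference year.
#' @param growth_rate Annual growth rate; defaults to the rate carried by
#'   `pop`.
#' @return An `hrh_population` with scaled counts and the reference year
#'   advanced by `year_offset`.
#' @export
project_population <- function(pop, year_offset,
                               growth_rate = attr(pop, "growth_rate")) {
  stopifnot(inherits(pop, "hrh_population"))
  year_offset <- check_count(year_offset, "year_offset", lower = 0)
  check_number(growth_rate, "growth_rate")
  if (growth_rate <= -1) abort("`growth_rate` must be greater than -1.")
  out <- pop
  out$count <- pop$count * (1 + growth_rate)^year_offset
  attr(out, "reference_year") <- attr(pop, "reference_year") + year_offset
  attr(out, "growth_rate") <- growth_rate
  out
}

#' Read or write a population table as CSV
#'
#' Columns: `age_band`, `sex`, `count`. The growth rate and reference year are
#' not stored in the CSV; they belong to the run configuration.
#'
#' @param path File path.
#' @param reference_year,growth_rate Passed to [hrh_population()] on read.
#' @return `read_population_csv()` returns an `hrh_population`;
#'   `write_population_csv()` returns `path` invisibly.
#' @export
read_population_csv <- function(path, reference_year = 0L, growth_rate = 0) {
  df <- readr::read_csv(path, col_types = readr::cols(
    age_band = readr::col_character(),
    sex = readr::col_character(),
    count = readr::col_double()
  ))
  hrh_population(df, reference_year = reference_year, growth_rate = growth_rate)
}

#' @param pop An [hrh_population()].
#' @rdname read_population_csv
#' @export
write_population_csv <- function(pop, path) {
  readr::write_csv(tibble::as_tibble(pop)[c("age_band", "sex", "count")], path)
  invisible(path)
}
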