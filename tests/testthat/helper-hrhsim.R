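# Shared fixtures for the suite, built in code.

# A fully static single-stratum system: no growth, no entrants, no exits,
# constant productivity. Gap is constant at every year by construction.
static_config <- function(required_fte_target = 10, supplied_fte = 4) {
  hrh_config(
    model = list(horizon = 10L),
    population = list(table = data.frame(age_band = "all", sex = "all",
                                         count = 10000),
                      growth_rate = 0),
    needs = list(table = data.frame(
      condition = "chronic", age_band = "all", sex = "all",
      rate = required_fte_target * 1000 / 10000,  # productivity 1000 below
      items_per_person_per_year = 1)),
    training = list(seats_per_year = 0, programme_length_years = 4L,
                    attrition_rate = 0, graduate_outmigration_rate = 0),
    supply = list(stock_total = supplied_fte, exit_rate = 0),
    workforce = list(participation_rate = 1, activity_rate = 1),
    requirement = list(public_sector_share = 1, productivity = 1000))
}

# Triple-loop reference for required_services, independent of the package's
# vectorised path: loops over conditions and population cells explicitly.
brute_force_required_services <- function(pop, needs, share) {
  total <- 0
  for (i in seq_len(nrow(needs))) {
    row_pop <- 0
    for (j in seq_len(nrow(pop))) {
      band_ok <- needs$age_band[i] == "all" ||
        needs$age_band[i] == pop$age_band[j]
      sex_ok <- needs$sex[i] == "all" || needs$sex[i] == pop$sex[j]
      if (band_ok && sex_ok) row_pop <- row_pop + pop$count[j]
    }
    total <- total + row_pop * needs$rate[i] * needs$items_per_person_per_year[i]
  }
  share * total
}

expect_rel_equal <- function(actual, expected, rel_tol = 1e-9) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(abs(actual - expected) / scale, rel_tol)
}
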