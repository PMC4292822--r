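#' Define a policy scenario as time-indexed parameter overrides
#'
#' A scenario is a named set of overrides layered on a baseline
#' configuration. Each override targets a dotted parameter path (for example
#' `"training.seats_per_year"`), starts at a given simulation year, and is
#' either a step (`set`: the value holds from the start year until
#' superseded), a rescaling of the baseline value (`scale`), or a compounding
#' annual rate applied to the baseline value (`grow`).
#'
#' @param name Scenario name (unique within a comparison).
#' @param overrides A list of overrides built with [override_set()],
#'   [override_scale()] or [override_grow()].
#' @param horizon_years Optional horizon override (positive integer).
#' @return A list of class `hrh_scenario`.
#' @export
scenario_spec <- function(name, overrides = list(), horizon_years = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("Scenario `name` must be a non-empty string.")
  }
  if (!is.null(horizon_years)) {
    horizon_years <- check_count(horizon_years, "horizon_years", lower = 1)
  }
  ok <- vapply(overrides, function(o) inherits(o, "hrh_override"), logical(1))
  if (length(overrides) > 0L && !all(ok)) {
    abort("All overrides must be built with override_set()/override_scale()/override_grow().")
  }
  structure(list(name = name, overrides = overrides,
                 horizon_years = horizon_years),
            class = "hrh_scenario")
}

new_override <- function(path, start_year, type, value) {
  if (!is.character(path) || length(path) != 1L) {
    abort("Override `path` must be a single dotted string.")
  }
  start_year <- check_count(start_year, "start_year", lower = 0)
  structure(list(path = path, start_year = start_year, type = type,
                 value = value),
            class = "hrh_override")
}

#' Build scenario overrides
#'
#' @param path Dotted parameter path into the configuration, for example
#'   `"supply.public_entry_fraction"`.
#' @param value Replacement value (`override_set`), multiplier on the
#'   baseline value (`override_scale`), or annual compounding rate
#'   (`override_grow`, applied from `start_year` onwards).
#' @param start_year First simulation year the override applies (default 0).
#' @return An object of class `hrh_override`.
#' @export
override_set <- function(path, value, start_year = 0L) {
  new_override(path, start_year, "set", value)
}

#' @rdname override_set
#' @export
override_scale <- function(path, value, start_year = 0L) {
  check_number(value, "value", lower = 0)
  new_override(path, start_year, "scale", value)
}

#' @rdname override_set
#' @export
override_grow <- function(path, value, start_year = 0L) {
  check_number(value, "value")
  if (value <= -1) abort("Growth override must be greater than -1.")
  new_override(path, start_year, "grow", value)
}

# Baseline value at a dotted path; unresolvable paths raise a config error
# naming the path.
config_value_at <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- config
  for (p in parts) {
    if (!is.list(node) || !p %in% names(node)) {
      abort(sprintf("Override path '%s' does not resolve against the baseline configuration.",
                    path), class = "hrh_config_error")
    }
    node <- node[[p]]
  }
  node
}

# Parameter value at a simulation year under a scenario's overrides. Among
# the overrides applicable at `year` (start_year <= year) the latest start
# wins; ties resolve to the last listed.
resolve_param <- function(config, scenario, path, year) {
  base <- config_value_at(config, path)
  value <- base
  best_start <- -Inf
  for (ov in scenario$overrides) {
    if (ov$path != path || ov$start_year > year) next
    if (ov$start_year < best_start) next
    best_start <- ov$start_year
    value <- switch(ov$type,
                    set = ov$value,
                    scale = base * ov$value,
                    grow = base * (1 + ov$value)^(year - ov$start_year))
  }
  value
}

# Validate that every override path resolves (errors name the first bad one).
check_override_paths <- function(config, scenario) {
  for (ov in scenario$overrides) config_value_at(config, ov$path)
  invisible(TRUE)
}

#' Run one scenario through the full projection engine
#'
#' Orchestrates training pipeline, supply stock-flow, FTE conversion and the
#' needs-based requirement over the horizon, producing the per-year gap
#' trajectory. The engine is fully deterministic: identical configurations
#' yield bit-identical trajectories. Year 0 reports the baseline identities
#' (supply FTE, required FTE, gap) before any dynamics, apart from overrides
#' that start at year 0.
#'
#' Annual event order within a step into year `t`: the training pipeline
#' advances (intake for year `t` enters; the graduating cohort, net of
#' attrition, leaves), graduates are routed to the stock per the active entry
#' mode, the stock loses exiters, ages, and gains entrants and in-migrants;
#' population and productivity compound by their annual rates.
#'
#' @param config A validated baseline [hrh_config()].
#' @param scenario An [scenario_spec()]; `NULL` runs the baseline unchanged.
#' @return A tibble of class `hrh_trajectory` with columns `year`,
#'   `headcount`, `fte_supply`, `fte_supply_no_sessions`, `required_items`,
#'   `required_fte`, `gap_fte` (`gap = required - supplied`; positive is a
#'   shortage), one row per year from 0 to the horizon.
#' @export
run_scenario <- function(config, scenario = NULL) {
  validate_config(config)
  if (is.null(scenario)) scenario <- scenario_spec("baseline")
  stopifnot(inherits(scenario, "hrh_scenario"))
  check_override_paths(config, scenario)
  H <- as.integer(scenario$horizon_years %||% config$model$horizon)
  rp <- function(path, year) resolve_param(config, scenario, path, year)

  mode <- rp("supply.entry_mode", 0)
  if (!mode %in% c("regional", "public_direct")) {
    abort("supply.entry_mode must be 'regional' or 'public_direct'.")
  }
  participation <- config_participation(config)
  # Tracked stock: regional licensed headcount, or (public_direct) the
  # employed public-sector sub-stock with participation baked in.
  initial_total <- if (mode == "regional") {
    config$supply$stock_total
  } else {
    config$workforce$employed_headcount %||%
      (participation * config$supply$stock_total)
  }
  stock <- config_stock(config, total = initial_total)
  needs <- config_needs(config)
  pop <- config_population(config)
  L <- config$training$programme_length_years

  # Pipeline position p graduates in the step into year p, so it entered at
  # year p - L; seat overrides starting at year 0 are therefore already in
  # the initial pipeline for cohorts entering at year >= 0.
  pipeline <- training_pipeline(
    vapply(seq_len(L), function(p) rp("training.seats_per_year", p - L),
           numeric(1)))

  productivity <- rp("requirement.productivity", 0)
  fte_at <- function(total, activity) {
    if (mode == "regional") total * participation * activity else total * activity
  }

  rows <- vector("list", H + 1L)
  record <- function(y, stock_total, pop_now, prod_now) {
    share <- rp("requirement.public_sector_share", y)
    activity <- rp("workforce.activity_rate", y)
    items <- required_services(pop_now, needs, share)
    req <- required_fte(items, prod_now)
    sup <- fte_at(stock_total, activity)
    tibble(year = y, headcount = stock_total, fte_supply = sup,
           fte_supply_no_sessions = fte_at(stock_total, 1),
           required_items = items, required_fte = req, gap_fte = req - sup)
  }
  rows[[1L]] <- record(0L, stock_total(stock), pop, productivity)

  for (y in seq_len(H)) {
    params_y <- training_params(
      seats_per_year = rp("training.seats_per_year", y),
      programme_length_years = L,
      attrition_rate = rp("training.attrition_rate", y),
      graduate_outmigration_rate = rp("training.graduate_outmigration_rate", y))
    adv <- advance_pipeline(pipeline, params_y,
                            intake = params_y$seats_per_year)
    pipeline <- adv$pipeline
    entry_frac <- if (mode == "regional") {
      1 - params_y$graduate_outmigration_rate
    } else {
      rp("supply.public_entry_fraction", y)
    }
    flows <- supply_flows(
      entrants_per_year = adv$graduates * entry_frac,
      in_migration_per_year = rp("supply.in_migration_per_year", y),
      entrant_age_distribution = config$supply$entrant_age)
    exits <- exit_schedule(rp("supply.exit_rate", y),
                           min_age = config$supply$min_age,
                           max_age = config$supply$max_age)
    if (!is.null(config$supply$exit_table)) {
      exits <- exit_schedule(config$supply$exit_table,
                             min_age = config$supply$min_age,
                             max_age = config$supply$max_age)
    }
    stock <- step_supply(stock, flows, exits)
    pop <- project_population(pop, 1L,
                              growth_rate = rp("population.growth_rate", y))
    productivity <- productivity *
      (1 + rp("workforce.productivity_growth_rate", y))
    rows[[y + 1L]] <- record(y, stock_total(stock), pop, productivity)
  }
  new_trajectory(dplyr::bind_rows(rows), scenario_name = scenario$name)
}

#' Compare policy scenarios against a common baseline
#'
#' Runs the baseline plus each scenario and summarises them: final-year gap,
#' gap reduction versus baseline (absolute and as a fraction of the baseline
#' final gap), and the first years, if any, at which the gap and the
#' no-sessions gap close (reach zero or below).
#'
#' @param config A validated baseline [hrh_config()].
#' @param scenarios A list of [scenario_spec()] objects with unique names.
#' @return A list of class `hrh_comparison` with elements `trajectories` (a
#'   long tibble with a `scenario` column) and `summary` (one row per
#'   scenario).
#' @export
compare_scenarios <- function(config, scenarios) {
  if (length(scenarios) < 1L) abort("Provide at least one scenario.")
  names_ <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(c("baseline", names_)) > 0L) {
    abort("Scenario names must be unique (and distinct from 'baseline').")
  }
  runs <- c(list(run_scenario(config)),
            lapply(scenarios, function(s) run_scenario(config, s)))
  all_names <- c("baseline", names_)
  long <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    dplyr::mutate(tibble::as_tibble(runs[[i]]), scenario = all_names[i],
                  .before = 1L)
  }))
  base_final <- dplyr::last(runs[[1L]]$gap_fte)
  first_year_at <- function(x, years) {
    i <- which(x <= 0)
    if (length(i) == 0L) NA_integer_ else years[min(i)]
  }
  summary <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]
    final_gap <- dplyr::last(tr$gap_fte)
    tibble(scenario = all_names[i],
           final_gap_fte = final_gap,
           gap_reduction_fte = base_final - final_gap,
           gap_reduction_frac = if (base_final != 0) {
             (base_final - final_gap) / base_final
           } else NA_real_,
           first_year_gap_closed = first_year_at(tr$gap_fte, tr$year),
           first_year_no_sessions_closed =
             first_year_at(tr$required_fte - tr$fte_supply_no_sessions,
                           tr$year))
  }))
  structure(list(trajectories = long, summary = summary),
            class = "hrh_comparison")
}

#' @export
print.hrh_comparison <- function(x, ...) {
  cat("<hrh_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Recover a population growth rate from a target final-year gap
#'
#' The baseline trajectory's final-year gap is continuous and strictly
#' increasing in the population growth rate (requirements scale with the
#' population while supply does not depend on it), so a target final gap
#' identifies at most one rate. Root-finding over the bounded interval
#' recovers it; targets outside the reachable range fail with the attainable
#' bounds in the message.
#'
#' @param config A validated baseline [hrh_config()].
#' @param target_final_gap Desired final-year gap in FTE.
#' @param horizon Projection horizon (default from the config).
#' @param bounds Growth-rate search interval (fraction/yr).
#' @param tol Acceptable |achieved - target| in FTE (default 0.01).
#' @return The growth rate (a single number) with attribute
#'   `achieved_final_gap`.
#' @export
calibrate_growth <- function(config, target_final_gap,
                             horizon = config$model$horizon,
                             bounds = c(-0.05, 0.10), tol = 0.01) {
  validate_config(config)
  gap_at <- function(g) {
    cfg <- config
    cfg$population$growth_rate <- g
    tr <- run_scenario(cfg, scenario_spec("calibration",
                                          horizon_years = horizon))
    dplyr::last(tr$gap_fte)
  }
  lo <- gap_at(bounds[1L]); hi <- gap_at(bounds[2L])
  if (abs(lo - target_final_gap) <= tol) {
    return(structure(bounds[1L], achieved_final_gap = lo))
  }
  if (abs(hi - target_final_gap) <= tol) {
    return(structure(bounds[2L], achieved_final_gap = hi))
  }
  if (target_final_gap < min(lo, hi) || target_final_gap > max(lo, hi)) {
    abort(sprintf(
      paste0("Target final gap %.3f FTE is not reachable: growth rates in ",
             "[%.3f, %.3f] span final gaps [%.3f, %.3f] FTE."),
      target_final_gap, bounds[1L], bounds[2L], min(lo, hi), max(lo, hi)),
      class = "hrh_calibration_error")
  }
  root <- uniroot(function(g) gap_at(g) - target_final_gap,
                  interval = bounds, tol = 1e-10)
  achieved <- gap_at(root$root)
  if (abs(achieved - target_final_gap) > tol) {
    abort(sprintf("Calibration did not converge: achieved %.4f vs target %.4f FTE.",
                  achieved, target_final_gap),
          class = "hrh_calibration_error")
  }
  structure(root$root, achieved_final_gap = achieved)
}

# shipped policy scenarios ------------------------------------------------

#' Shipped policy scenarios
#'
#' The four policy levers rehearsed for the Jamaica baseline: a relative
#' increase in training seats; routing a fixed fraction of graduates
#' directly into the public-sector workforce (`entry_mode = "public_direct"`);
#' compounded annual productivity growth; and the retention and productivity
#' levers combined.
#'
#' @param factor Seat multiplier (2 doubles enrolment).
#' @param fraction Graduate-to-public-entry fraction.
#' @param rate Annual productivity growth rate.
#' @param start_year First year the lever applies.
#' @return An [scenario_spec()].
#' @export
scenario_seat_increase <- function(factor = 2, start_year = 0L) {
  scenario_spec(sprintf("seat_increase_%d%%", round((factor - 1) * 100)),
                list(override_scale("training.seats_per_year", factor,
                                    start_year)))
}

#' @rdname scenario_seat_increase
#' @export
scenario_public_retention <- function(fraction = 0.25, start_year = 0L) {
  scenario_spec(sprintf("retention_%d%%", round(fraction * 100)),
                list(override_set("supply.entry_mode", "public_direct",
                                  start_year),
                     override_set("supply.public_entry_fraction", fraction,
                                  start_year)))
}

#' @rdname scenario_seat_increase
#' @export
scenario_productivity_growth <- function(rate = 0.05, start_year = 0L) {
  scenario_spec(sprintf("productivity_plus_%g%%_per_year", rate * 100),
                list(override_set("workforce.productivity_growth_rate", rate,
                                  start_year)))
}

#' @rdname scenario_seat_increase
#' @export
scenario_combined <- function(fraction = 0.25, rate = 0.05, start_year = 0L) {
  scenario_spec("combined_retention_productivity",
                list(override_set("supply.entry_mode", "public_direct",
                                  start_year),
                     override_set("supply.public_entry_fraction", fraction,
                                  start_year),
                     override_set("workforce.productivity_growth_rate", rate,
                                  start_year)))
}

#' @return `jamaica_scenarios()`: a named list of the four shipped scenarios.
#' @rdname scenario_seat_increase
#' @export
jamaica_scenarios <- function() {
  list(seat_increase = scenario_seat_increase(2),
       retention = scenario_public_retention(0.25),
       productivity = scenario_productivity_growth(0.05),
       combined = scenario_combined(0.25, 0.05))
}
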