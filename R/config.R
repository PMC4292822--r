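#' Assemble a model configuration
#'
#' A configuration gathers every input the simulation engine needs: the
#' population block, the needs table, training-programme parameters, supply
#' (stock, exits, inflow routing), workforce rates, and the requirement
#' parameters. It is an ordinary nested list (class `hrh_config`) that can be
#' round-tripped through a YAML document with [write_config()] /
#' [load_config()].
#'
#' The `supply$entry_mode` field selects how graduate inflow is routed:
#' \describe{
#'   \item{`"regional"`}{graduates net of out-migration join the regional
#'     licensed stock; participation converts the stock to the employed
#'     public-sector headcount every year.}
#'   \item{`"public_direct"`}{the tracked stock is the public-sector employed
#'     sub-stock itself (initialised as `employed_headcount`), and
#'     `supply$public_entry_fraction` of each year's graduates enters it
#'     directly. Participation is then already baked into the stock and is
#'     not applied again.}
#' }
#' The two routings are never mixed: exactly one is active per run.
#'
#' @param population,needs,training,supply,workforce,requirement,model Named
#'   lists overriding the corresponding default blocks (see
#'   [default_config()]).
#' @return A list of class `hrh_config`.
#' @export
hrh_config <- function(population = list(), needs = list(),
                       training = list(), supply = list(),
                       workforce = list(), requirement = list(),
                       model = list()) {
  cfg <- default_config()
  user <- list(population = population, needs = needs, training = training,
               supply = supply, workforce = workforce,
               requirement = requirement, model = model)
  # data.frame values replace wholesale (modifyList would merge column-wise)
  merge_block <- function(base, new) {
    for (nm in names(new)) base[[nm]] <- new[[nm]]
    base
  }
  for (block in names(user)) {
    cfg[[block]] <- merge_block(cfg[[block]], user[[block]])
  }
  class(cfg) <- "hrh_config"
  cfg
}

#' Default configuration blocks
#'
#' A minimal, schema-valid single-stratum configuration. Every field is
#' documented here once; [hrh_config()] overlays user values on top.
#'
#' @return A named list of blocks.
#' @export
default_config <- function() {
  list(
    model = list(
      horizon = 15L,          # years simulated beyond year 0
      base_year = 0L          # calendar year of year 0 (labelling only)
    ),
    population = list(
      table = data.frame(age_band = "all", sex = "all", count = 0),
      growth_rate = 0         # uniform annual growth, fraction/yr
    ),
    needs = list(
      table = data.frame(condition = character(), age_band = character(),
                         sex = character(), rate = numeric(),
                         items_per_person_per_year = numeric())
    ),
    training = list(
      seats_per_year = 0,
      programme_length_years = 4L,
      attrition_rate = 0,
      graduate_outmigration_rate = 0
    ),
    supply = list(
      entry_mode = "regional",      # or "public_direct"
      public_entry_fraction = 0,    # used by entry_mode = "public_direct"
      in_migration_per_year = 0,
      entrant_age = 23L,
      min_age = 23L,
      max_age = 75L,
      stock_total = 0,
      stock_mean_age = 36,
      stock_table = NULL,           # optional explicit age, headcount table
      exit_rate = 0,                # flat annual exit rate
      exit_table = NULL             # optional age, exit_rate table
    ),
    workforce = list(
      participation_rate = NULL,    # derived from employed_headcount if NULL
      employed_headcount = NULL,    # optional observed employed headcount
      activity_rate = 1,
      fte_hours_per_week = 40,
      activity_cap = 1.5,
      productivity_growth_rate = 0
    ),
    requirement = list(
      public_sector_share = 1,
      productivity = 1              # items per FTE per year
    )
  )
}

#' Participation rate implied by a configuration
#'
#' Uses `workforce$participation_rate` when set; otherwise derives it as
#' `employed_headcount / stock_total` (both paths the source data may take).
#'
#' @param config An [hrh_config()].
#' @return A fraction in \[0, 1\].
#' @export
config_participation <- function(config) {
  w <- config$workforce
  if (!is.null(w$participation_rate)) return(w$participation_rate)
  if (!is.null(w$employed_headcount)) {
    if (config$supply$stock_total <= 0) {
      abort("Cannot derive participation: stock_total is not positive.")
    }
    return(w$employed_headcount / config$supply$stock_total)
  }
  abort("Configuration sets neither participation_rate nor employed_headcount.")
}

#' Validate a configuration, reporting every violation
#'
#' Checks types, bounds and cross-field consistency and either returns the
#' configuration invisibly or aborts with an itemized report listing all
#' violations (not just the first).
#'
#' @param config An [hrh_config()].
#' @return `config`, invisibly, when valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  note <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x >= lo && x <= hi

  m <- config$model
  note(num_in(m$horizon, 0, Inf), "model.horizon must be a non-negative number")
  p <- config$population
  note(is.data.frame(p$table) && all(c("age_band", "sex", "count") %in%
                                       names(p$table)),
       "population.table must have columns age_band, sex, count")
  if (is.data.frame(p$table) && "count" %in% names(p$table)) {
    note(all(p$table$count >= 0), "population counts must be non-negative")
  }
  note(num_in(p$growth_rate, -1 + 1e-12, Inf) && p$growth_rate > -1,
       "population.growth_rate must be a number greater than -1")

  n <- config$needs$table
  note(is.data.frame(n) && all(c("condition", "rate",
                                 "items_per_person_per_year") %in% names(n)),
       "needs.table must have columns condition, rate, items_per_person_per_year")
  if (is.data.frame(n) && "rate" %in% names(n) && nrow(n) > 0L) {
    note(all(n$rate >= 0 & n$rate <= 1), "needs rates must lie in [0, 1]")
    note(all(n$items_per_person_per_year >= 0),
         "needs items_per_person_per_year must be non-negative")
  }

  tr <- config$training
  note(num_in(tr$seats_per_year, 0, Inf),
       "training.seats_per_year must be non-negative")
  note(num_in(tr$programme_length_years, 1, Inf),
       "training.programme_length_years must be >= 1")
  note(num_in(tr$attrition_rate, 0, 1),
       "training.attrition_rate must lie in [0, 1]")
  note(num_in(tr$graduate_outmigration_rate, 0, 1),
       "training.graduate_outmigration_rate must lie in [0, 1]")

  s <- config$supply
  note(s$entry_mode %in% c("regional", "public_direct"),
       "supply.entry_mode must be 'regional' or 'public_direct'")
  note(num_in(s$public_entry_fraction, 0, 1),
       "supply.public_entry_fraction must lie in [0, 1]")
  note(num_in(s$in_migration_per_year, 0, Inf),
       "supply.in_migration_per_year must be non-negative")
  note(num_in(s$stock_total, 0, Inf), "supply.stock_total must be non-negative")
  note(num_in(s$exit_rate, 0, 1), "supply.exit_rate must lie in [0, 1]")
  note(num_in(s$min_age, 0, Inf) && num_in(s$max_age, 0, Inf) &&
         s$min_age <= s$max_age,
       "supply age range must satisfy 0 <= min_age <= max_age")
  note(num_in(s$entrant_age, s$min_age %||% 0, s$max_age %||% Inf),
       "supply.entrant_age must lie within [min_age, max_age]")

  w <- config$workforce
  if (!is.null(w$participation_rate)) {
    note(num_in(w$participation_rate, 0, 1),
         "workforce.participation_rate must lie in [0, 1]")
  } else {
    note(!is.null(w$employed_headcount) &&
           num_in(w$employed_headcount, 0, Inf),
         "workforce must set participation_rate or a non-negative employed_headcount")
  }
  note(num_in(w$activity_rate, 1e-12, Inf),
       "workforce.activity_rate must be strictly positive")
  note(num_in(w$fte_hours_per_week, 1e-12, Inf),
       "workforce.fte_hours_per_week must be strictly positive")
  note(is.numeric(w$productivity_growth_rate) &&
         w$productivity_growth_rate > -1,
       "workforce.productivity_growth_rate must be greater than -1")

  r <- config$requirement
  note(num_in(r$public_sector_share, 0, 1),
       "requirement.public_sector_share must lie in [0, 1]")
  note(num_in(r$productivity, 1e-12, Inf),
       "requirement.productivity must be strictly positive")

  if (length(problems) > 0L) {
    abort(c("Invalid model configuration:",
            setNames(problems, rep("x", length(problems)))),
          class = "hrh_config_error")
  }
  invisible(config)
}

# data.frame <-> plain-list helpers for YAML persistence ------------------

df_to_records <- function(df) {
  if (is.null(df)) return(NULL)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

records_to_df <- function(recs) {
  if (is.null(recs) || length(recs) == 0L) return(NULL)
  dplyr::bind_rows(lapply(recs, tibble::as_tibble))
}

#' Load a model configuration from a YAML document
#'
#' The document mirrors the blocks of [hrh_config()]. Tabular fields
#' (`population.table`, `needs.table`, `supply.stock_table`,
#' `supply.exit_table`) may be inline row-records or a `path` to a CSV file
#' resolved relative to the document. The loaded configuration is passed
#' through [validate_config()], which reports every violation at once.
#'
#' @param path Path to the YAML configuration.
#' @return A validated [hrh_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  take_table <- function(block, field) {
    x <- block[[field]]
    if (is.null(x)) return(NULL)
    if (is.list(x) && !is.null(x$path)) {
      f <- x$path
      if (!file.exists(f)) f <- file.path(base_dir, x$path)
      if (!file.exists(f)) {
        abort(sprintf("Referenced file not found: %s", x$path))
      }
      return(as.data.frame(readr::read_csv(f, show_col_types = FALSE)))
    }
    as.data.frame(records_to_df(x))
  }
  blocks <- list()
  for (b in c("population", "needs", "training", "supply", "workforce",
              "requirement", "model")) {
    blocks[[b]] <- raw[[b]] %||% list()
  }
  for (spec in list(c("population", "table"), c("needs", "table"),
                    c("supply", "stock_table"), c("supply", "exit_table"))) {
    tab <- take_table(blocks[[spec[1]]], spec[2])
    if (!is.null(tab)) blocks[[spec[1]]][[spec[2]]] <- tab
  }
  cfg <- hrh_config(population = blocks$population, needs = blocks$needs,
                    training = blocks$training, supply = blocks$supply,
                    workforce = blocks$workforce,
                    requirement = blocks$requirement, model = blocks$model)
  validate_config(cfg)
  cfg
}

#' Write a model configuration to a YAML document
#'
#' Tabular fields are written inline as row-records so the document is
#' self-contained; `load_config(write_config(x))` reproduces `x`
#' semantically.
#'
#' @param config An [hrh_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$population$table <- df_to_records(out$population$table)
  out$needs$table <- df_to_records(out$needs$table)
  out$supply$stock_table <- df_to_records(out$supply$stock_table)
  out$supply$exit_table <- df_to_records(out$supply$exit_table)
  out <- rapply(out, function(x) x, how = "replace")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# realised model objects from a config ------------------------------------

config_population <- function(config) {
  hrh_population(config$population$table,
                 reference_year = config$model$base_year,
                 growth_rate = config$population$growth_rate)
}

config_needs <- function(config) hrh_needs(config$needs$table)

config_training <- function(config) {
  tr <- config$training
  training_params(seats_per_year = tr$seats_per_year,
                  programme_length_years = tr$programme_length_years,
                  attrition_rate = tr$attrition_rate,
                  graduate_outmigration_rate = tr$graduate_outmigration_rate)
}

config_exits <- function(config) {
  s <- config$supply
  if (!is.null(s$exit_table)) {
    exit_schedule(s$exit_table, min_age = s$min_age, max_age = s$max_age)
  } else {
    exit_schedule(s$exit_rate, min_age = s$min_age, max_age = s$max_age)
  }
}

# Initial stock at the configured total; an explicit stock_table wins over
# the regenerable triangular placement.
config_stock <- function(config, total = config$supply$stock_total) {
  s <- config$supply
  if (!is.null(s$stock_table)) {
    tab <- s$stock_table
    base_total <- sum(tab$headcount)
    if (base_total > 0 && !isTRUE(all.equal(base_total, total))) {
      tab$headcount <- tab$headcount * total / base_total
    }
  } else {
    tab <- triangular_age_counts(total, min_age = s$min_age,
                                 max_age = min(s$max_age, 62L))
  }
  provider_stock(tab, year = 0L, min_age = s$min_age, max_age = s$max_age)
}

config_rates <- function(config) {
  w <- config$workforce
  workforce_rates(participation_rate = config_participation(config),
                  activity_rate = w$activity_rate,
                  fte_hours_per_week = w$fte_hours_per_week,
                  productivity_growth_rate = w$productivity_growth_rate,
                  activity_cap = w$activity_cap)
}
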