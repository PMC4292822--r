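trajectory_cols <- c("year", "headcount", "fte_supply",
                     "fte_supply_no_sessions", "required_items",
                     "required_fte", "gap_fte")

new_trajectory <- function(df, scenario_name = "baseline") {
  df <- as_tibble(df)[trajectory_cols]
  structure(df, class = c("hrh_trajectory", class(tibble())),
            scenario = scenario_name)
}

#' @export
print.hrh_trajectory <- function(x, ...) {
  cat(sprintf("<hrh_trajectory> scenario '%s', years %d-%d, final gap %.1f FTE\n",
              attr(x, "scenario"), min(x$year), max(x$year),
              dplyr::last(x$gap_fte)))
  NextMethod()
}

#' Write a gap trajectory to CSV
#'
#' Column order is the fixed contract `year, headcount, fte_supply,
#' fte_supply_no_sessions, required_items, required_fte, gap_fte`. Numeric
#' columns are formatted with a fixed number of decimal places so identical
#' trajectories produce byte-identical files.
#'
#' @param traj An `hrh_trajectory` (or any data frame with the contract
#'   columns).
#' @param path Output path.
#' @param digits Decimal places for the real-valued columns (default 6).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6L) {
  df <- as_tibble(traj)
  missing <- setdiff(trajectory_cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0("Trajectory is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  df <- df[trajectory_cols]
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  out <- data.frame(year = as.integer(df$year),
                    lapply(df[trajectory_cols[-1L]], fmt),
                    check.names = FALSE)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a gap trajectory written by [write_trajectory()]
#' @param path CSV path.
#' @return An `hrh_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), .default = readr::col_double()))
  new_trajectory(df)
}

#' Round trajectory values the way planning reports print them
#'
#' Gaps and FTE figures to the nearest ten, headcounts to integers, service
#' items to the nearest hundred. Reporting rounding is applied only here,
#' never inside the simulation state.
#'
#' @param traj An `hrh_trajectory`.
#' @return A tibble with the same columns, rounded.
#' @export
report_rounding <- function(traj) {
  df <- as_tibble(traj)
  dplyr::mutate(df,
                headcount = round(.data$headcount),
                fte_supply = round(.data$fte_supply, 1),
                fte_supply_no_sessions = round(.data$fte_supply_no_sessions, 1),
                required_items = 100 * round(.data$required_items / 100),
                required_fte = 10 * round(.data$required_fte / 10),
                gap_fte = 10 * round(.data$gap_fte / 10))
}

# broom-style tidiers -----------------------------------------------------

#' Tidy a gap trajectory into long format
#'
#' @param x An `hrh_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `scenario`, `year`, `measure`, `value`.
#' @export
tidy.hrh_trajectory <- function(x, ...) {
  df <- dplyr::mutate(as_tibble(x), scenario = attr(x, "scenario"),
                      .before = 1L)
  tidyr::pivot_longer(df, -c("scenario", "year"),
                      names_to = "measure", values_to = "value")
}

#' One-row summary of a gap trajectory
#'
#' @param x An `hrh_trajectory`.
#' @param ... Unused.
#' @return A tibble with the scenario name, horizon, initial and final gap,
#'   and the first years the gap and no-sessions gap close (NA if never).
#' @export
glance.hrh_trajectory <- function(x, ...) {
  first_at <- function(v) {
    i <- which(v <= 0)
    if (length(i) == 0L) NA_integer_ else x$year[min(i)]
  }
  tibble(scenario = attr(x, "scenario"),
         horizon = max(x$year),
         initial_gap_fte = x$gap_fte[1L],
         final_gap_fte = dplyr::last(x$gap_fte),
         first_year_gap_closed = first_at(x$gap_fte),
         first_year_no_sessions_closed =
           first_at(x$required_fte - x$fte_supply_no_sessions))
}

#' @export
tidy.hrh_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$trajectories, -c("scenario", "year"),
                      names_to = "measure", values_to = "value")
}

#' @export
glance.hrh_comparison <- function(x, ...) x$summary

# plots -------------------------------------------------------------------

#' Plot the supply-requirement gap over time
#'
#' One line per scenario, simulation year on the horizontal axis, gap (FTE;
#' positive = shortage) on the vertical, with a dashed zero reference.
#'
#' @param object An `hrh_trajectory` or `hrh_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrh_trajectory <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), scenario = attr(object, "scenario"))
  gap_plot(df)
}

#' @rdname autoplot.hrh_trajectory
#' @export
autoplot.hrh_comparison <- function(object, ...) {
  gap_plot(object$trajectories)
}

gap_plot <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$gap_fte,
                                   colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Simulation year", y = "Gap (required - supplied FTE)",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hrh_trajectory
#' @export
plot_gap <- function(object, ...) autoplot(object, ...)
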