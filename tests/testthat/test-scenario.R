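test_that("year 0 reproduces the baseline identities before any dynamics", {
  tr <- run_scenario(jamaica_baseline())
  expect_equal(tr$year, 0:15)
  expect_equal(tr$headcount[1], 55)
  expect_equal(tr$fte_supply[1], 37.5)
  expect_equal(tr$fte_supply_no_sessions[1], 30)
  expect_equal(tr$required_fte[1], 150, tolerance = 1e-9)
  expect_equal(tr$gap_fte[1], 112.5, tolerance = 1e-9)
  # gap algebra holds exactly at every year
  expect_equal(tr$gap_fte, tr$required_fte - tr$fte_supply)
  expect_equal(tr$required_fte, tr$required_items / 16800)
})

test_that("a static system keeps a constant gap at every year", {
  tr <- run_scenario(static_config(required_fte_target = 10, supplied_fte = 4))
  expect_equal(tr$gap_fte, rep(6, 11), tolerance = 1e-12)
  expect_equal(tr$headcount, rep(4, 11), tolerance = 1e-12)
})

test_that("seat doubling leaves supply and gap bit-identical for one programme length", {
  cfg <- jamaica_baseline()
  base <- run_scenario(cfg)
  doubled <- run_scenario(cfg, scenario_seat_increase(2))
  first4 <- 1:4  # years 0-3
  for (col in c("headcount", "fte_supply", "fte_supply_no_sessions", "gap_fte")) {
    expect_identical(doubled[[col]][first4], base[[col]][first4])
  }
  expect_false(identical(doubled$headcount[5], base$headcount[5]))
  expect_true(all(doubled$headcount[5:16] > base$headcount[5:16]))
})

test_that("a scenario with no overrides reproduces the baseline exactly", {
  cfg <- jamaica_baseline()
  cmp <- compare_scenarios(cfg, list(scenario_spec("copy")))
  s <- cmp$summary
  expect_equal(s$gap_reduction_fte[s$scenario == "copy"], 0)
  expect_equal(s$gap_reduction_frac[s$scenario == "copy"], 0)
})

test_that("duplicate scenario names are rejected", {
  cfg <- static_config()
  expect_error(compare_scenarios(cfg, list(scenario_spec("a"),
                                           scenario_spec("a"))))
  expect_error(compare_scenarios(cfg, list(scenario_spec("baseline"))))
  expect_error(compare_scenarios(cfg, list()))
})

test_that("the engine is deterministic: repeat runs are bit-identical", {
  cfg <- jamaica_baseline()
  scen <- scenario_combined()
  expect_identical(as.data.frame(run_scenario(cfg, scen)),
                   as.data.frame(run_scenario(cfg, scen)))
  cfg2 <- generate_random_case(77)
  expect_identical(as.data.frame(run_scenario(cfg2)),
                   as.data.frame(run_scenario(cfg2)))
})

test_that("policy levers move the gap monotonically at every year", {
  cfg <- jamaica_baseline()
  base <- run_scenario(cfg)
  eps <- 1e-9
  # more seats never widens the gap
  more_seats <- run_scenario(cfg, scenario_seat_increase(1.5))
  expect_true(all(more_seats$gap_fte <= base$gap_fte + eps))
  # faster productivity growth never widens the gap
  faster <- run_scenario(cfg, scenario_productivity_growth(0.03))
  expect_true(all(faster$gap_fte <= base$gap_fte + eps))
  # higher public-entry fraction never widens the gap (within public_direct)
  r20 <- run_scenario(cfg, scenario_public_retention(0.20))
  r30 <- run_scenario(cfg, scenario_public_retention(0.30))
  expect_true(all(r30$gap_fte <= r20$gap_fte + eps))
  # higher population growth never narrows the gap
  slower_pop <- cfg; slower_pop$population$growth_rate <- 0.01
  expect_true(all(base$gap_fte >= run_scenario(slower_pop)$gap_fte - eps))
  # a uniformly higher need rate never narrows the gap
  higher_need <- cfg
  higher_need$needs$table$rate <- higher_need$needs$table$rate * 1.1
  expect_true(all(run_scenario(higher_need)$gap_fte >= base$gap_fte - eps))
})

test_that("overrides starting later leave earlier years at baseline values", {
  cfg <- jamaica_baseline()
  late <- scenario_spec("late_productivity",
                        list(override_set("workforce.productivity_growth_rate",
                                          0.05, start_year = 5L)))
  tr <- run_scenario(cfg, late)
  base <- run_scenario(cfg)
  expect_identical(tr$required_fte[1:5], base$required_fte[1:5])
  expect_true(all(tr$required_fte[7:16] < base$required_fte[7:16]))
})

test_that("growth calibration inverts the final-year gap", {
  cfg <- static_config(required_fte_target = 10, supplied_fte = 4)
  g <- calibrate_growth(cfg, target_final_gap = 6)
  expect_equal(as.numeric(g), 0, tolerance = 1e-6)
  # infeasible target below anything reachable
  err <- expect_error(calibrate_growth(cfg, target_final_gap = -100),
                      class = "hrh_calibration_error")
  expect_match(conditionMessage(err), "not reachable")
})

test_that("scenario stubs round-trip through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  dir <- withr::local_tempdir()
  write_fixture_files(dir, jamaica_baseline())
  scen <- read_scenario(file.path(dir, "scenarios", "retention.yaml"))
  expect_equal(scen$name, "retention_25%")
  cfg <- jamaica_baseline()
  expect_identical(as.data.frame(run_scenario(cfg, scen)),
                   as.data.frame(run_scenario(cfg, scenario_public_retention(0.25))))
})

test_that("tidiers and plots expose the trajectory tidily", {
  tr <- run_scenario(jamaica_baseline())
  td <- tidy(tr)
  expect_setequal(unique(td$measure),
                  c("headcount", "fte_supply", "fte_supply_no_sessions",
                    "required_items", "required_fte", "gap_fte"))
  gl <- glance(tr)
  expect_equal(gl$initial_gap_fte, 112.5, tolerance = 1e-9)
  expect_equal(gl$horizon, 15)
  cmp <- compare_scenarios(jamaica_baseline(), list(scenario_combined()))
  expect_s3_class(glance(cmp), "tbl_df")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
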