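test_that("one supply step applies exits then aging then entries", {
  stock <- provider_stock(triangular_age_counts(55), year = 2008)
  flows <- supply_flows(entrants_per_year = 7)
  exits <- exit_schedule(0.05)
  nxt <- step_supply(stock, flows, exits)
  expect_equal(stock_total(nxt), 55 * 0.95 + 7, tolerance = 1e-12)  # 59.25
  expect_identical(attr(nxt, "year"), 2009L)
})

test_that("with no exits and no flows the stock just ages", {
  stock <- provider_stock(data.frame(age = c(30L, 40L), headcount = c(3, 4)))
  nxt <- step_supply(stock, supply_flows(0), exit_schedule(0))
  expect_equal(stock_total(nxt), 7)
  expect_equal(nxt$headcount[nxt$age %in% c(31L, 41L)], c(3, 4))
  expect_equal(sum(nxt$headcount[!nxt$age %in% c(31L, 41L)]), 0)
})

test_that("a flat exit rate of one empties the stock", {
  stock <- provider_stock(triangular_age_counts(55))
  nxt <- step_supply(stock, supply_flows(0), exit_schedule(1))
  expect_equal(stock_total(nxt), 0)
})

test_that("the top age is absorbing", {
  stock <- provider_stock(data.frame(age = 75L, headcount = 10),
                          min_age = 23L, max_age = 75L)
  nxt <- step_supply(stock, supply_flows(0), exit_schedule(0.1))
  expect_equal(nxt$headcount[nxt$age == 75L], 9)
  expect_equal(stock_total(nxt), 9)
})

test_that("headcount is conserved exactly at every step", {
  withr::local_seed(404)
  for (rep in 1:25) {
    counts <- data.frame(age = sample(23:70, 8), headcount = stats::runif(8, 0, 20))
    stock <- provider_stock(counts)
    rate_tab <- data.frame(age = 23:75, exit_rate = stats::runif(53, 0, 0.3))
    exits <- exit_schedule(rate_tab)
    flows <- supply_flows(stats::runif(1, 0, 10), stats::runif(1, 0, 3))
    lost <- sum(stock$headcount * rate_tab$exit_rate[match(stock$age, rate_tab$age)])
    nxt <- step_supply(stock, flows, exits)
    expect_equal(stock_total(nxt),
                 stock_total(stock) - lost + flows$entrants_per_year +
                   flows$in_migration_per_year,
                 tolerance = 1e-12)
    expect_true(all(nxt$headcount >= 0))
  }
})

test_that("flat-exit projections match the geometric-series closed form", {
  withr::local_seed(405)
  for (rep in 1:200) {
    n0 <- stats::runif(1, 0, 300)
    e <- stats::runif(1, 0, 0.5)
    G <- stats::runif(1, 0, 20)
    horizon <- sample(0:30, 1)
    stock <- provider_stock(triangular_age_counts(n0))
    states <- project_supply(stock, supply_flows(G), exit_schedule(e), horizon)
    for (t in seq_along(states)) {
      expect_rel_equal(stock_total(states[[t]]),
                       closed_form_supply(n0, e, G, t - 1L))
    }
  }
})

test_that("closed_form_supply handles its edge cases", {
  expect_equal(closed_form_supply(55, 0.05, 7, 0), 55)
  expect_equal(closed_form_supply(55, 0.05, 0, 15), 55 * 0.95^15)
  expect_equal(closed_form_supply(55, 0, 7, 10), 125)
  # spec'd Jamaica-like case, evaluated independently as an explicit sum
  direct <- 55 * 0.95^15 + 7 * sum(0.95^(0:14))
  expect_equal(closed_form_supply(55, 0.05, 7, 15), direct, tolerance = 1e-12)
  expect_error(closed_form_supply(55, 1.5, 7, 15))
  expect_error(closed_form_supply(55, -0.1, 7, 15))
})

test_that("stocks concentrated at high-exit ages shrink faster", {
  exits <- exit_schedule(data.frame(age = 23:75,
                                    exit_rate = seq(0.01, 0.4, length.out = 53)))
  young <- provider_stock(data.frame(age = 30L, headcount = 50))
  old <- provider_stock(data.frame(age = 65L, headcount = 50))
  flows <- supply_flows(0)
  expect_lte(stock_total(step_supply(old, flows, exits)),
             stock_total(step_supply(young, flows, exits)))
})

test_that("project_supply returns horizon + 1 states and rejects bad horizons", {
  stock <- provider_stock(triangular_age_counts(10))
  expect_length(project_supply(stock, supply_flows(1), exit_schedule(0.1), 0), 1)
  out <- project_supply(stock, supply_flows(1), exit_schedule(0.1), 5)
  expect_length(out, 6)
  expect_error(project_supply(stock, supply_flows(1), exit_schedule(0.1), -1))
})

test_that("the triangular placement has mean age exactly 36 over ages 23-62", {
  tab <- triangular_age_counts(55, 23L, 62L)
  expect_equal(sum(tab$headcount), 55)
  expect_equal(sum(tab$age * tab$headcount) / sum(tab$headcount), 36)
})

test_that("retirement-scenario hook scales exit rates above a cut-off", {
  exits <- exit_schedule(0.05)
  adj <- adjust_exit_schedule(exits, 55L, 3)
  expect_equal(unique(adj$exit_rate[adj$age < 55]), 0.05)
  expect_equal(unique(adj$exit_rate[adj$age >= 55]), 0.15)
  capped <- adjust_exit_schedule(exits, 55L, 50)
  expect_equal(unique(capped$exit_rate[capped$age >= 55]), 1)
})

test_that("stock tables round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  stock <- provider_stock(triangular_age_counts(55), year = 2008)
  write_stock_csv(stock, tmp)
  back <- read_stock_csv(tmp, year = 2008)
  expect_equal(as.data.frame(back), as.data.frame(stock))
})
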