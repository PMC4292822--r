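test_that("population projection compounds growth uniformly", {
  pop <- hrh_population(1330000, reference_year = 2008, growth_rate = 0)
  expect_equal(total_population(project_population(pop, 15)), 1330000)
  expect_equal(total_population(project_population(pop, 1, growth_rate = 0.01)),
               1343300)
  # independent evaluation of the compound-growth closed form
  expect_equal(total_population(project_population(pop, 15, growth_rate = 0.02)),
               1330000 * 1.02^15, tolerance = 1e-12)

  strat <- hrh_population(data.frame(
    age_band = c("0-17", "18+", "0-17", "18+"),
    sex = c("female", "female", "male", "male"),
    count = c(100, 300, 120, 280)))
  grown <- project_population(strat, 7, growth_rate = 0.03)
  expect_equal(grown$count / total_population(grown),
               strat$count / total_population(strat))
  expect_error(project_population(pop, -1))
  expect_error(project_population(pop, 3, growth_rate = -1))
})

test_that("required_services multiplies population, rate, level and share", {
  empty <- hrh_population(data.frame(age_band = "all", sex = "all", count = 0))
  needs1 <- hrh_needs(data.frame(condition = "c1", rate = 0.10,
                                 items_per_person_per_year = 5))
  expect_equal(required_services(empty, needs1, 0.3), 0)
  pop <- hrh_population(1000)
  expect_equal(required_services(pop, needs1, 0.3), 150)
})

test_that("needs rows referencing absent strata are rejected", {
  pop <- hrh_population(data.frame(age_band = c("0-17", "18+"),
                                   sex = "all", count = c(400, 600)))
  bad <- hrh_needs(data.frame(condition = "c1", age_band = "65+", sex = "all",
                              rate = 0.1, items_per_person_per_year = 2))
  expect_error(required_services(pop, bad, 1),
               class = "hrh_stratification_error")
  ok <- hrh_needs(data.frame(condition = "c1", age_band = "18+", sex = "all",
                             rate = 0.1, items_per_person_per_year = 2))
  expect_equal(required_services(pop, ok, 1), 600 * 0.1 * 2)
})

test_that("required_services matches a brute-force triple loop on random tables", {
  withr::local_seed(401)
  for (rep in 1:40) {
    n_strata <- sample(1:4, 1)
    n_cond <- sample(1:5, 1)
    bands <- paste0("b", seq_len(n_strata))
    pop <- hrh_population(data.frame(
      age_band = rep(bands, each = 2), sex = rep(c("f", "m"), n_strata),
      count = stats::runif(2 * n_strata, 0, 1e5)))
    needs <- hrh_needs(data.frame(
      condition = paste0("c", seq_len(n_cond)),
      age_band = sample(c(bands, "all"), n_cond, replace = TRUE),
      sex = sample(c("f", "m", "all"), n_cond, replace = TRUE),
      rate = stats::runif(n_cond, 0, 1),
      items_per_person_per_year = stats::runif(n_cond, 0, 12)))
    share <- stats::runif(1)
    expect_rel_equal(required_services(pop, needs, share),
                     brute_force_required_services(pop, needs, share))
  }
})

test_that("required_services is linear and monotone in each factor", {
  withr::local_seed(402)
  pop <- hrh_population(data.frame(age_band = c("a", "b"), sex = "all",
                                   count = c(5000, 2500)))
  needs <- hrh_needs(data.frame(
    condition = c("c1", "c2"), age_band = c("all", "a"), sex = "all",
    rate = c(0.2, 0.05), items_per_person_per_year = c(4, 9)))
  base <- required_services(pop, needs, 0.5)
  for (k in c(0, 0.3, 2, 7)) {
    pop_k <- pop; pop_k$count <- pop_k$count * k
    expect_equal(required_services(pop_k, needs, 0.5), k * base,
                 tolerance = 1e-12)
  }
  for (k in c(0, 0.3, 0.9)) {  # rates stay in [0, 1]; linear in rates too
    needs_k <- needs; needs_k$rate <- needs$rate * k
    expect_equal(required_services(pop, needs_k, 0.5), k * base,
                 tolerance = 1e-12)
  }
  # share bounds and monotonicity in share
  expect_equal(required_services(pop, needs, 0), 0)
  expect_equal(required_services(pop, needs, 1), 2 * base, tolerance = 1e-12)
  # raising a single rate or level never decreases the result
  up <- needs; up$rate[2] <- up$rate[2] + 0.1
  expect_gte(required_services(pop, up, 0.5), base)
  up2 <- needs; up2$items_per_person_per_year[1] <- 11
  expect_gte(required_services(pop, up2, 0.5), base)
})

test_that("required_fte divides services by productivity, exactly once", {
  expect_equal(required_fte(0, 16800), 0)
  expect_equal(required_fte(2520000, 16800), 150)
  expect_equal(required_fte(16800, 16800), 1)
  expect_error(required_fte(100, 0))
  expect_error(required_fte(100, -5))
  # monotone: higher productivity never raises the requirement
  expect_lte(required_fte(2520000, 17000), required_fte(2520000, 16800))
})

test_that("population and needs tables round-trip through CSV", {
  tmp <- withr::local_tempdir()
  pop <- hrh_population(data.frame(age_band = c("0-17", "18+"),
                                   sex = c("f", "m"), count = c(10.5, 20.25)),
                        reference_year = 2008, growth_rate = 0.01)
  f1 <- file.path(tmp, "pop.csv")
  write_population_csv(pop, f1)
  back <- read_population_csv(f1, reference_year = 2008, growth_rate = 0.01)
  expect_equal(as.data.frame(back), as.data.frame(pop))

  needs <- jamaica_condition_table()
  f2 <- file.path(tmp, "needs.csv")
  write_needs_csv(needs, f2)
  expect_equal(as.data.frame(read_needs_csv(f2)), as.data.frame(needs))
})

test_that("invalid needs tables are rejected", {
  expect_error(hrh_needs(data.frame(condition = "c", rate = 1.2,
                                    items_per_person_per_year = 1)))
  expect_error(hrh_needs(data.frame(condition = "c", rate = 0.5,
                                    items_per_person_per_year = -1)))
  expect_error(hrh_needs(data.frame(condition = c("c", "c"), rate = 0.1,
                                    items_per_person_per_year = 1)))
})
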