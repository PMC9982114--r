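# Population profiles, rate tables, exposure partitioning.

test_that("the packaged case-study profile reproduces its subpopulations", {
  pop <- frome_gateway_fixture()$population
  expect_equal(population_total(pop), 9241)
  expect_equal(population_total(select_subpopulation(pop, 18, 120)), 6927)
  expect_equal(population_total(select_subpopulation(pop, 35, 120)), 3262)
  expect_equal(population_total(select_subpopulation(pop, 65, 120)), 588)
  expect_equal(population_total(select_subpopulation(pop, 0, 7)), 1223)
  expect_equal(population_total(select_subpopulation(pop, 9, 13)), 583)
  expect_equal(population_total(select_subpopulation(pop, 18, 120, sex = "male")),
               3616)
})

test_that("empty age bands return an empty profile, not an error", {
  pop <- make_population()
  expect_equal(population_total(select_subpopulation(pop, 200, 300)), 0)
  expect_error(select_subpopulation(pop, 30, 30), "age_min < age_max")
})

test_that("select_subpopulation partitions counts exactly", {
  pop <- make_population(n = 5000)
  ab <- population_total(select_subpopulation(pop, 0, 40))
  bc <- population_total(select_subpopulation(pop, 40, 70))
  ac <- population_total(select_subpopulation(pop, 0, 70))
  expect_identical(ab + bc, ac)
})

test_that("mean_remaining_life is the count-weighted mean", {
  expect_equal(mean_remaining_life(
    population_profile(0:2, c(1, 1, 1), c(10, 20, 30))), 20)
  expect_equal(mean_remaining_life(
    population_profile(c(50), 1, 82.3)), 82.3)
  # constant LE, any counts
  expect_equal(mean_remaining_life(
    population_profile(0:9, runif(10, 1, 99), rep(40, 10))), 40)
  # invariant under uniform scaling of counts
  p <- make_population()
  p2 <- population_profile(p$age, p$count * 17, p$life_expectancy)
  expect_equal(mean_remaining_life(p2), mean_remaining_life(p))
  expect_error(mean_remaining_life(select_subpopulation(p, 200, 300)),
               "empty")
})

test_that("split_exposure conserves persons and validates Pe", {
  s <- split_exposure(1000, 0.5)
  expect_equal(s$ne, 500); expect_equal(s$nu, 500)
  expect_equal(split_exposure(9241, 0)$nu, 9241)
  expect_equal(split_exposure(3262, 1)$ne, 3262)
  for (Pe in runif(25)) {
    n <- runif(1, 1, 1e6)
    s <- split_exposure(n, Pe)
    expect_identical(s$ne + s$nu, s$n)   # exact conservation
    expect_equal(s$n, n)
    expect_equal(s$Pe, s$ne / s$n)
    expect_equal(s$Pu, 1 - s$Pe)
  }
  expect_error(split_exposure(100, 1.2), "Pe")
  expect_error(split_exposure(0, 0.5), "n must be")
})

test_that("lookup_rate handles direct, weighted and error cases", {
  rates <- make_rates()
  # direct single-row lookup
  expect_equal(lookup_rate(rates, "asthma", c(0, 120))$annual_rate, 0.01)
  expect_equal(lookup_rate(rates, "asthma", c(0, 120))$duration_years, 8)
  # band spanning rows -> count-weighted average (100 at 0.01, 300 at 0.03)
  r2 <- rate_table(data.frame(
    outcome_id = "x", age_min = c(0, 50), age_max = c(50, 100),
    rate_kind = "incidence", annual_rate = c(0.01, 0.03),
    duration_years = c(1, 1)))
  prof <- population_profile(c(25, 75), c(100, 300), c(60, 20))
  expect_equal(lookup_rate(r2, "x", c(0, 100), profile = prof)$annual_rate,
               0.025)
  # unknown outcome
  expect_error(lookup_rate(rates, "gout", c(0, 120)), "missing-rate")
  # spanning band without a profile
  expect_error(lookup_rate(rates, "diabetes", c(18, 120)), "profile")
  # overlapping rate rows are rejected at construction
  expect_error(rate_table(data.frame(
    outcome_id = "x", age_min = c(0, 40), age_max = c(50, 100),
    rate_kind = "incidence", annual_rate = 0.01, duration_years = 1)),
    "overlapping")
})

test_that("population and rate CSVs round-trip, male_fraction optional", {
  pop <- frome_gateway_fixture()$population
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path, label = "frome_gateway")
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
  # a three-column CSV (no male_fraction) defaults to 0.5
  df <- data.frame(age = 0:1, count = c(10, 10), life_expectancy = c(80, 79))
  utils::write.csv(df, path, row.names = FALSE)
  expect_equal(read_population(path)$male_fraction, c(0.5, 0.5))
  rates <- make_rates()
  write_rates(rates, path)
  expect_equal(as.data.frame(read_rates(path)), as.data.frame(rates))
})

test_that("rate table validation enforces probability bounds", {
  expect_error(rate_table(data.frame(
    outcome_id = "x", age_min = 0, age_max = 10, rate_kind = "incidence",
    annual_rate = 1.4, duration_years = 1)), "\\[0, 1\\]")
  expect_error(rate_table(data.frame(
    outcome_id = "x", age_min = 0, age_max = 10, rate_kind = "incidence",
    annual_rate = 0.1, duration_years = -2)), "duration")
})
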