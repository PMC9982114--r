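# Synthetic-data generator and the packaged case study.

test_that("generated libraries are deterministic and span the typologies", {
  spec <- fixture_spec(seed = 20, n_pathways = 170)
  a <- generate_pathway_library(spec)
  b <- generate_pathway_library(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 170)
  expect_gte(length(unique(a$typology)), 5)
  expect_true(any(a$odds_ratio < 1))          # some protective
  expect_true(any(!is.na(a$threshold_cmp)))   # some thresholded
  # a different seed gives a different library
  c <- generate_pathway_library(fixture_spec(seed = 21, n_pathways = 170))
  expect_false(identical(a$odds_ratio, c$odds_ratio))
})

test_that("a degenerate or_range of (1,1) yields a null-effect library", {
  pw <- generate_pathway_library(
    fixture_spec(seed = 2, n_pathways = 40, or_range = c(1, 1)))
  expect_true(all(pw$odds_ratio == 1))
  split <- split_exposure(1000, 0.5)
  effects <- vapply(pw$odds_ratio, function(or)
    attributable_cases(split, 0.1, or)$Cattributed, numeric(1))
  expect_true(all(effects == 0))
})

test_that("generated populations are sized, monotone and deterministic", {
  spec <- fixture_spec(seed = 9, population_size = 9241)
  pop <- generate_population(spec)
  expect_equal(population_total(pop), 9241)
  expect_true(all(diff(pop$life_expectancy) < 0))
  expect_gt(pop$life_expectancy[pop$age == 0],
            pop$life_expectancy[pop$age == 80])
  expect_identical(as.data.frame(generate_population(spec)),
                   as.data.frame(pop))
})

test_that("fixture generation restores the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(generate_pathway_library(fixture_spec(seed = 1, n_pathways = 5)))
  invisible(generate_population(fixture_spec(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("the packaged case study states its documented constants", {
  fx <- frome_gateway_fixture()
  expect_equal(population_total(fx$population), 9241)
  expect_equal(fx$params$onsite_residents, 3000)
  expect_equal(fx$params$homes * fx$params$occupancy + fx$params$students,
               3000)
  expect_equal(fx$params$green_space_ha, 2.37)
  expect_equal(fx$params$ndvi_site, 0.15)
  expect_equal(fx$params$ndvi_riverside_park, 0.29)
  expect_equal(fx$scenarios$baseline$metrics$green_space_area_ha, 2.37)
  # the diabetes threshold pathway carries the 0.7 ha activation value
  dia <- fx$pathways[fx$pathways$id == "fg_open_diabetes", ]
  expect_equal(dia$threshold_value, 0.7)
  expect_equal(dia$threshold_cmp, ">=")
})

test_that("every fixture artifact passes its consuming validators cleanly", {
  fx <- frome_gateway_fixture()
  expect_silent(validate_pathways(as.data.frame(fx$pathways)))
  expect_silent(rate_table(as.data.frame(fx$rates)))
  expect_silent(unit_value_table(as.data.frame(fx$unit_values)))
  for (nm in names(fx$scenarios)) {
    expect_silent(run_scenario(fx$scenarios[[nm]], fx$pathways, fx$population,
                               fx$rates, fx$unit_values))
  }
})

test_that("back-solved parameters reproduce the published pairs end-to-end", {
  fx <- frome_gateway_fixture()
  run1 <- function(nm) run_scenario(fx$scenarios[[nm]], fx$pathways,
                                    fx$population, fx$rates, fx$unit_values)
  base <- run1("baseline")
  # (expected, attributable) pairs as printed, to presentation rounding
  check <- function(rep, id, expected, attributable) {
    row <- rep[rep$pathway_id == id, ]
    expect_equal(round(row$cases_expected), expected, label = id)
    expect_equal(round(row$attributable), attributable, label = id)
  }
  check(base, "fg_parkuse_diabetes", 20, -3)
  check(base, "fg_parkuse_weight", 979, -127)
  check(base, "fg_prox_activity", 4295, 2632)
  check(base, "fg_prox_mental", 463, 125)
  check(base, "fg_large_activity", 3671, 1432)
  check(base, "fg_quality_pleasant", 463, 125)
  check(base, "fg_quality_safety", 463, 125)
  s1 <- run1("s1_policy")
  check(s1, "fg_improve_parkuse", 2134, 171)
  check(s1, "fg_parkuse_weight", 979, -139)
  expect_equal(s1[s1$pathway_id == "fg_ndvi_cancer", "attributable"], -0.23,
               tolerance = 1e-9)
  s2 <- run1("s2_single_space")
  check(s2, "fg_open_diabetes", 41, -10)
  check(s2, "fg_ndvi_asthma", 18, 8)
  check(s2, "fg_ndvi_weight", 216, -41)
  # the documented inconsistent asthma row back-solves to 4.8 (renders 60%)
  prox_asthma <- base[base$pathway_id == "fg_prox_asthma", ]
  expect_equal(prox_asthma$attributable, 4.8, tolerance = 1e-9)
  expect_equal(prox_asthma$pct_change, 60L)
  # the back-solved money anecdotes: -GBP 22.7m diabetes saving in S2 and
  # ~GBP 41.5m mortality value at the NDVI sensitivity threshold
  expect_equal(s2[s2$pathway_id == "fg_open_diabetes", "value_total"],
               -22.7e6, tolerance = 1e-6)
  sw <- sensitivity_sweep(fx$scenarios$baseline, "ndvi_increase", 0.24,
                          fx$pathways, fx$population, fx$rates,
                          fx$unit_values)
  expect_equal(sw[[1]]$report[sw[[1]]$report$outcome == "premature_mortality",
                              "value_total"],
               -41.5e6, tolerance = 1e-6)
})

test_that("write_fixtures emits a complete, loadable input set", {
  dir <- withr::local_tempdir()
  write_fixtures(dir, seed = 4)
  expect_true(all(file.exists(file.path(dir, c(
    "pathways.csv", "population.csv", "rates.csv", "unit_values.csv",
    "generated_pathways.csv", "config.yaml",
    file.path("scenarios", "baseline.yaml"))))))
  cfg <- suppressMessages(read_config(file.path(dir, "config.yaml")))
  expect_equal(nrow(cfg$pathways), 14)
  expect_equal(length(cfg$scenarios), 4)
  # file round-trip preserves the engine's output exactly
  fx <- frome_gateway_fixture()
  rep_mem <- run_scenario(fx$scenarios$baseline, fx$pathways, fx$population,
                          fx$rates, fx$unit_values)
  rep_file <- run_scenario(cfg$scenarios$baseline, cfg$pathways,
                           cfg$population, cfg$rates, cfg$unit_values)
  expect_equal(rep_file$attributable, rep_mem$attributable, tolerance = 1e-9)
})
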