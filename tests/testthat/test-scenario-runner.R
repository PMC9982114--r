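# Scenario assembly, percent-change reporting, comparisons, sweeps, CLI I/O.

fx <- frome_gateway_fixture()
run_fx <- function(nm) run_scenario(fx$scenarios[[nm]], fx$pathways,
                                    fx$population, fx$rates, fx$unit_values)

test_that("percent change uses half-away-from-zero integer rounding", {
  expect_equal(percent_change(-3, 20), -15L)
  expect_equal(percent_change(125, 463), 27L)
  expect_equal(percent_change(-127, 979), -13L)
  expect_equal(percent_change(2632, 4295), 61L)
  expect_equal(percent_change(1432, 3671), 39L)
  expect_equal(percent_change(0, 50), 0L)
  expect_equal(percent_change(1, 8), 13L)    # 12.5 rounds away from zero
  expect_equal(percent_change(-1, 8), -13L)
  expect_dash(percent_change(3, 0))
  expect_error(percent_change(1, -2), "expected")
})

test_that("the baseline run reproduces the case-study morbidity table", {
  rep <- run_fx("baseline")
  morb <- rep[rep$outcome_kind == "morbidity", ]
  expect_equal(nrow(morb), 7)
  expect_equal(morb$N, c(6927, 1223, 583, 583, 6927, 3262, 3262))
  expect_equal(morb$cases_expected, c(2, 18, 216, 8, 41, 20, 979),
               tolerance = 1e-9)
  active <- morb[morb$active, ]
  expect_equal(active$pct_change, c(60L, -15L, -13L))
  # behaviour/wellbeing rows carry the published percents
  beh <- rep[rep$outcome_kind == "behaviour_wellbeing" & rep$active, ]
  expect_equal(beh$pct_change, c(61L, 27L, 39L, 27L, 27L))
})

test_that("every emitted pct_change equals percent_change recomputed", {
  for (nm in names(fx$scenarios)) {
    rep <- run_fx(nm)
    act <- rep[rep$active & !is.na(rep$attributable), ]
    expect_equal(act$pct_change,
                 percent_change(act$attributable, act$cases_expected),
                 label = nm)
  }
})

test_that("zero exposure everywhere yields zero attributable effects", {
  scn <- fx$scenarios$baseline
  scn$pathway_exposure <- lapply(scn$pathway_exposure, function(x) 0)
  rep <- run_scenario(scn, fx$pathways, fx$population, fx$rates,
                      fx$unit_values)
  expect_true(all(rep$attributable[rep$active] == 0))
  expect_true(all(rep$value_total[rep$active] == 0))
})

test_that("validation fails fast on missing metric, Pe, rate or unit value", {
  scn <- fx$scenarios$s2_single_space
  scn$metrics$largest_new_open_space_ha <- NULL
  expect_error(run_scenario(scn, fx$pathways, fx$population, fx$rates,
                            fx$unit_values), "largest_new_open_space_ha")
  scn <- fx$scenarios$baseline
  scn$pathway_exposure$fg_prox_asthma <- NULL
  expect_error(run_scenario(scn, fx$pathways, fx$population, fx$rates,
                            fx$unit_values), "fg_prox_asthma")
  rates2 <- fx$rates[fx$rates$outcome_id != "diabetes", ]
  expect_error(run_scenario(fx$scenarios$baseline, fx$pathways, fx$population,
                            rate_table(as.data.frame(rates2)), fx$unit_values),
               "diabetes")
  uv2 <- fx$unit_values[fx$unit_values$outcome_id != "park_use", ]
  expect_error(run_scenario(fx$scenarios$baseline, fx$pathways, fx$population,
                            fx$rates, unit_value_table(as.data.frame(uv2))),
               "park_use")
})

test_that("increasing one Pe with OR > 1 never decreases its attribution", {
  scn <- fx$scenarios$baseline
  pes <- seq(0, 1, by = 0.2)
  vals <- vapply(pes, function(pe) {
    s <- scn; s$pathway_exposure$fg_prox_activity <- pe
    r <- run_scenario(s, fx$pathways, fx$population, fx$rates, fx$unit_values)
    r$attributable[r$pathway_id == "fg_prox_activity"]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("scenario comparison renders dashes, totals and unique keys", {
  cmp <- compare_scenarios(run_fx("baseline"),
                           list(S2 = run_fx("s2_single_space"),
                                S3 = run_fx("s3_dispersed")))
  dia <- cmp[cmp$environment_change == "Size of public open spaces", ]
  expect_equal(dia$S2, "-10")
  expect_equal(dia$S3, "-")        # threshold not reached when dispersed
  expect_equal(dia$Baseline, "-")
  expect_equal(cmp$environment_change[nrow(cmp)], "Total")
  expect_match(attr(cmp, "note"), "double counting")
  # identical scenarios give identical columns
  cmp2 <- compare_scenarios(run_fx("baseline"),
                            list(A = run_fx("baseline"),
                                 B = run_fx("baseline")))
  expect_identical(cmp2$A, cmp2$Baseline)
  expect_identical(cmp2$A, cmp2$B)
  # empty scenario list -> baseline-only table
  cmp3 <- compare_scenarios(run_fx("baseline"))
  expect_equal(setdiff(names(cmp3), c("environment_change", "outcome")),
               "Baseline")
  # duplicate keys are an aggregation error
  dup <- run_fx("baseline")
  expect_error(compare_scenarios(rbind(dup, dup[1, ])), "duplicate")
})

test_that("a metric sweep recomputes threshold activation per value", {
  sw <- sensitivity_sweep(fx$scenarios$baseline, "ndvi_increase",
                          c(0.05, 0.14, 0.24), fx$pathways, fx$population,
                          fx$rates, fx$unit_values)
  expect_length(sw, 3)
  expect_equal(vapply(sw, `[[`, numeric(1), "value"), c(0.05, 0.14, 0.24))
  mort <- lapply(sw, function(s)
    s$report[s$report$outcome == "premature_mortality", ])
  expect_dash(mort[[1]]$attributable)
  expect_dash(mort[[2]]$attributable)
  expect_equal(mort[[3]]$attributable, -3, tolerance = 1e-9)
  # sweeping to the current value reproduces the plain run
  sw1 <- sensitivity_sweep(fx$scenarios$baseline, "ndvi_increase", 0,
                           fx$pathways, fx$population, fx$rates,
                           fx$unit_values)
  expect_equal(as.data.frame(sw1[[1]]$report),
               as.data.frame(run_fx("baseline")))
  expect_error(sensitivity_sweep(fx$scenarios$baseline, "ndvi_increase",
                                 numeric(0), fx$pathways, fx$population,
                                 fx$rates, fx$unit_values), "empty")
  expect_error(sensitivity_sweep(fx$scenarios$baseline, "nope", 1,
                                 fx$pathways, fx$population, fx$rates,
                                 fx$unit_values), "nope")
})

test_that("the config-driven run writes reports and a manifest", {
  dir <- withr::local_tempdir()
  write_fixtures(dir, seed = 5)
  expect_true(haus_validate(file.path(dir, "config.yaml")))
  out <- file.path(dir, "out")
  rep <- suppressMessages(haus_run(file.path(dir, "config.yaml"), out))
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "valuation.csv")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$tool, "haus")
  expect_equal(manifest$scenario, "baseline")
  got <- utils::read.csv(file.path(out, "report.csv"),
                         colClasses = "character")
  expect_equal(names(got),
               c("characteristic", "environment_change", "outcome",
                 "population_label", "N", "cases_expected", "attributable",
                 "pct_change", "value_total"))
  # valuation conserves bearers
  val <- utils::read.csv(file.path(out, "valuation.csv"))
  expect_equal(val$individual_family + val$employer + val$healthcare_provider +
                 val$state, val$total, tolerance = 1e-9)
  # comparison and sweep entry points
  cmp <- suppressMessages(haus_compare(file.path(dir, "config.yaml"),
                                       out_dir = file.path(dir, "cmp")))
  expect_true(file.exists(file.path(dir, "cmp", "comparison.csv")))
  sw <- suppressMessages(haus_sweep(file.path(dir, "config.yaml"),
                                    "ndvi_increase", c(0, 0.24),
                                    file.path(dir, "sweep")))
  expect_true(file.exists(file.path(dir, "sweep", "report_0.24.csv")))
})

test_that("the CLI dispatches and rejects unknown commands", {
  dir <- withr::local_tempdir()
  suppressMessages(haus_cli(c("fixtures", "--seed", "3", "--out", dir)))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  suppressMessages(haus_cli(c("run", file.path(dir, "config.yaml"),
                              "--out", file.path(dir, "o"))))
  expect_true(file.exists(file.path(dir, "o", "report.csv")))
  expect_error(haus_cli("frobnicate"), "unknown command")
})
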