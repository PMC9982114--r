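# Shared builders for tiny in-code fixtures.

# One-row pathway with overridable fields.
make_pathway <- function(...) {
  defaults <- list(
    id = "p1", typology = "Natural Environment", characteristic = "Green space",
    environment_change = "NDVI increase", outcome_id = "asthma",
    outcome_kind = "morbidity", odds_ratio = 1.2,
    exposure_metric = "ndvi", threshold_cmp = NA_character_,
    threshold_value = NA_real_, age_min = 0, age_max = 120,
    sex = NA_character_, source_note = "test"
  )
  args <- utils::modifyList(defaults, list(...))
  impact_pathways(as.data.frame(args, stringsAsFactors = FALSE))
}

# Small flat population: `n` persons spread over the given ages.
make_population <- function(n = 1000, ages = 0:99, le0 = 82, slope = 0.8,
                            label = "test") {
  population_profile(ages, rep(n / length(ages), length(ages)),
                     pmax(2, le0 - slope * ages), label = label)
}

make_rates <- function() {
  rate_table(data.frame(
    outcome_id = c("asthma", "diabetes", "diabetes", "deaths_all"),
    age_min = c(0, 18, 35, 0),
    age_max = c(120, 35, 120, 120),
    rate_kind = c("incidence", "incidence", "incidence", "mortality"),
    annual_rate = c(0.01, 0.005, 0.007, 0.009),
    duration_years = c(8, 20, 20, NA),
    stringsAsFactors = FALSE
  ))
}

make_unit_values <- function() {
  unit_value_table(data.frame(
    outcome_id = c("asthma", "diabetes", "deaths_all"),
    per_case = c(1000, 50000, NA),
    per_year = c(125, 2500, NA),
    vsl = c(NA, NA, 2e6),
    vsly = c(NA, NA, 60000),
    comp_medical = c(600, 20000, NA),
    comp_productivity_informal = c(300, 20000, NA),
    comp_disutility = c(100, 10000, NA),
    share_individual = 0.4, share_employer = 0.1,
    share_healthcare = 0.3, share_state = 0.2,
    stringsAsFactors = FALSE
  ))
}

expect_dash <- function(x) expect_true(is.na(x))
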