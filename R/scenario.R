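# Scenario assembly and reporting: joins pathways, populations, rates and
# unit values into baseline/scenario evaluations, computes comparison tables
# and percent changes, and backs the command-line interface.

#' Construct a scenario
#'
#' A scenario states the environmental conditions being appraised: the values
#' of the exposure metrics pathways may be thresholded on (e.g. NDVI, the
#' largest newly provided contiguous open space in hectares), the proportion
#' of each pathway's target population that is exposed, and the project
#' timeline.
#'
#' @param name Scenario name.
#' @param population_ref Label of the population profile the scenario applies
#'   to.
#' @param metrics Named list/vector of finite metric values.
#' @param pathway_exposure Named list/vector mapping pathway id to the exposed
#'   proportion `Pe` in `[0, 1]`.
#' @param timeline A `haus_timeline`.
#' @return A `haus_scenario` list.
#' @export
scenario <- function(name, population_ref = "", metrics = list(),
                     pathway_exposure = list(),
                     timeline = project_timeline()) {
  metrics <- as.list(metrics)
  pathway_exposure <- as.list(pathway_exposure)
  if (length(metrics) > 0 && any(!is.finite(unlist(metrics)))) {
    stop("scenario validation error: metrics must be finite", call. = FALSE)
  }
  pe <- unlist(pathway_exposure)
  if (length(pe) > 0 && any(!is.finite(pe) | pe < 0 | pe > 1)) {
    stop("scenario validation error: all Pe must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(timeline, "haus_timeline"))
  structure(
    list(name = name, population_ref = population_ref, metrics = metrics,
         pathway_exposure = pathway_exposure, timeline = timeline),
    class = "haus_scenario"
  )
}

#' Read a scenario from a YAML file
#'
#' Expected keys: `name`, `population_ref`, `metrics` (map), `pathway_exposure`
#' (map), and `timeline` with `years`, optional `cap_years` and `ramp`.
#'
#' @param path YAML file path.
#' @return A `haus_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop("scenario load error: file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  tl <- y$timeline
  timeline <- project_timeline(
    T_intervention = if (is.null(tl$years)) 25L else tl$years,
    lag_ramp = if (is.null(tl$ramp)) c(0.2, 0.4, 0.6, 0.8, 1.0) else tl$ramp,
    cap_years = if (is.null(tl$cap_years)) 25L else tl$cap_years
  )
  scenario(
    name = if (is.null(y$name)) tools::file_path_sans_ext(basename(path)) else y$name,
    population_ref = if (is.null(y$population_ref)) "" else y$population_ref,
    metrics = if (is.null(y$metrics)) list() else y$metrics,
    pathway_exposure = if (is.null(y$pathway_exposure)) list() else y$pathway_exposure,
    timeline = timeline
  )
}

#' Write a scenario to YAML
#' @param scn A `haus_scenario`.
#' @param path Output path.
#' @export
write_scenario <- function(scn, path) {
  yaml::write_yaml(list(
    name = scn$name,
    population_ref = scn$population_ref,
    metrics = scn$metrics,
    pathway_exposure = scn$pathway_exposure,
    timeline = list(years = scn$timeline$T_intervention,
                    cap_years = scn$timeline$cap_years,
                    ramp = scn$timeline$lag_ramp)
  ), path, precision = 17)
  invisible(path)
}

# Human-readable label for a pathway's target population, e.g. "Adults >18",
# "Children 9-12", "Men >18".
label_population <- function(age_min, age_max, sex = NA) {
  group <- if (age_max <= 18) "Children" else "Adults"
  if (!is.na(sex) && sex == "male") group <- "Men"
  if (!is.na(sex) && sex == "female") group <- "Women"
  if (age_max >= 100) {
    paste0(group, " >", format(age_min))
  } else if (age_min == 0) {
    paste0(group, " <", format(age_max))
  } else {
    paste0(group, " ", format(age_min), "-", format(age_max - 1))
  }
}

#' Percent change of attributable over expected cases
#'
#' Integer percent, rounded half away from zero (so -12.97 renders as -13 and
#' 61.28 as 61). When expected is zero the change is undefined and the dash
#' sentinel `NA` is returned.
#'
#' @param attributable Attributable cases/deaths per year (may be negative).
#' @param expected Expected cases/deaths per year without the exposure, >= 0.
#' @return Integer percent, or `NA` (rendered as a dash).
#' @export
percent_change <- function(attributable, expected) {
  stopifnot(length(attributable) == length(expected))
  if (any(expected < 0, na.rm = TRUE)) {
    stop("report error: expected cases must be >= 0", call. = FALSE)
  }
  dash <- is.na(expected) | expected == 0 | is.na(attributable)
  pct <- 100 * attributable / ifelse(dash, NA_real_, expected)
  out <- as.integer(sign(pct) * floor(abs(pct) + 0.5))
  out[dash] <- NA_integer_
  out
}

# Fail-fast validation pass before any computation.
validate_scenario_inputs <- function(scn, pathways, population, rates,
                                     unit_values) {
  if (nzchar(scn$population_ref) && nzchar(attr(population, "label")) &&
      !identical(scn$population_ref, attr(population, "label"))) {
    stop("configuration error: scenario '", scn$name, "' references population '",
         scn$population_ref, "' but profile '", attr(population, "label"),
         "' was supplied", call. = FALSE)
  }
  for (i in seq_len(nrow(pathways))) {
    pw <- pathways[i, ]
    if (!is.na(pw$threshold_cmp) &&
        is.null(scn$metrics[[pw$exposure_metric]])) {
      stop("configuration error: pathway '", pw$id, "' requires scenario ",
           "metric '", pw$exposure_metric, "' which is missing", call. = FALSE)
    }
    pe <- scn$pathway_exposure[[pw$id]]
    if (is.null(pe)) {
      stop("configuration error: scenario '", scn$name, "' has no exposed ",
           "proportion (Pe) for pathway '", pw$id, "'", call. = FALSE)
    }
    kind <- if (pw$outcome_kind == "mortality") "mortality" else "incidence"
    hit <- rates$outcome_id == pw$outcome_id & rates$rate_kind == kind &
      rates$age_max > pw$age_min & rates$age_min < pw$age_max
    if (!any(hit)) {
      stop("configuration error: no ", kind, " rate for outcome '",
           pw$outcome_id, "' required by pathway '", pw$id, "'", call. = FALSE)
    }
    if (!(pw$outcome_id %in% unit_values$outcome_id)) {
      stop("configuration error: no unit value for outcome '", pw$outcome_id,
           "' required by pathway '", pw$id, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate every pathway under a scenario
#'
#' The full estimation pipeline, per pathway: decide activation from the
#' scenario metrics; select the pathway's target subpopulation; split it by
#' the scenario's exposed proportion; compute the annual attributable effect
#' (cases for morbidity/behaviour pathways, deaths and life-years lost for
#' mortality pathways); accumulate the lag-ramped project-lifetime total; and
#' monetize it (per-case societal cost for morbidity, VSLY x life-years for
#' mortality). Inputs are validated before any computation; inactive pathways
#' emit a row whose attributable entries are the dash sentinel `NA`.
#'
#' @param scn A `haus_scenario`.
#' @param pathways A `haus_pathways` library (already filtered to the
#'   pathways under appraisal).
#' @param population A `haus_population`.
#' @param rates A `haus_rates`.
#' @param unit_values A `haus_unit_values`.
#' @return A `haus_report` data.frame with one row per pathway and columns
#'   `characteristic`, `environment_change`, `outcome`, `population_label`,
#'   `N`, `cases_expected`, `attributable`, `pct_change`, `value_total`, plus
#'   bookkeeping columns `pathway_id`, `outcome_kind` and `active`. Full
#'   valuation breakdowns are attached as attribute `"valuations"`.
#' @export
run_scenario <- function(scn, pathways, population, rates, unit_values) {
  stopifnot(inherits(scn, "haus_scenario"))
  validate_scenario_inputs(scn, pathways, population, rates, unit_values)
  n_pw <- nrow(pathways)
  rows <- vector("list", n_pw)
  valuations <- vector("list", n_pw)
  for (i in seq_len(n_pw)) {
    pw <- pathways[i, ]
    active <- is_active(pw, scn$metrics)
    subpop <- select_subpopulation(population, pw$age_min, pw$age_max,
                                   sex = pw$sex)
    n_sub <- population_total(subpop)
    if (!(n_sub > 0)) {
      stop("evaluation error: pathway '", pw$id, "' targets an empty ",
           "subpopulation [", pw$age_min, ", ", pw$age_max, ")", call. = FALSE)
    }
    kind <- if (pw$outcome_kind == "mortality") "mortality" else "incidence"
    rt <- lookup_rate(rates, pw$outcome_id, c(pw$age_min, pw$age_max),
                      rate_kind = kind, profile = subpop)
    split <- split_exposure(n_sub, scn$pathway_exposure[[pw$id]])
    if (pw$outcome_kind == "mortality") {
      res <- attributable_deaths(split, rt$annual_rate, pw$odds_ratio)
      res <- attributable_yll(res, mean_remaining_life(subpop))
      expected <- res$Dexpected
      attributable <- res$Dattributed
      lifetime_yll <- total_effect(res$YLLattributed, scn$timeline)
      val <- monetize(lifetime_yll, unit_values, basis = "vsly",
                      timeline = scn$timeline, outcome_id = pw$outcome_id)
    } else {
      res <- attributable_cases(split, rt$annual_rate, pw$odds_ratio)
      expected <- res$Cexpected
      attributable <- res$Cattributed
      lifetime_cases <- total_effect(attributable, scn$timeline)
      val <- monetize(lifetime_cases, unit_values, basis = "per_case",
                      timeline = scn$timeline, outcome_id = pw$outcome_id)
    }
    rows[[i]] <- data.frame(
      pathway_id = pw$id,
      characteristic = pw$characteristic,
      environment_change = pw$environment_change,
      outcome = pw$outcome_id,
      outcome_kind = pw$outcome_kind,
      population_label = label_population(pw$age_min, pw$age_max, pw$sex),
      N = n_sub,
      cases_expected = expected,
      attributable = if (active) attributable else NA_real_,
      pct_change = if (active) percent_change(attributable, expected)
                   else NA_integer_,
      value_total = if (active) val$total else NA_real_,
      active = active,
      stringsAsFactors = FALSE
    )
    valuations[i] <- list(if (active) val else NULL)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "scenario") <- scn$name
  attr(report, "valuations") <- stats::setNames(valuations, pathways$id)
  class(report) <- c("haus_report", "data.frame")
  report
}

# Presentation rounding: counts >= 1 in magnitude render as integers,
# 0 < |x| < 1 as two decimals; NA renders as the dash. Internal precision is
# never rounded -- this is output formatting only.
format_count <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("-")
    if (v == 0) return("0")
    if (abs(v) < 1) return(sprintf("%.2f", v))
    sprintf("%d", as.integer(sign(v) * floor(abs(v) + 0.5)))
  }, character(1))
}

#' Format a report for presentation
#'
#' Renders the dash sentinel, integer/2-decimal count rounding, percent signs
#' and 2-decimal money. Used to write `report.csv`.
#'
#' @param report A `haus_report`.
#' @return A character data.frame with the report columns.
#' @export
format_report <- function(report) {
  data.frame(
    characteristic = report$characteristic,
    environment_change = report$environment_change,
    outcome = report$outcome,
    population_label = report$population_label,
    N = format_count(report$N),
    cases_expected = format_count(report$cases_expected),
    attributable = format_count(report$attributable),
    pct_change = ifelse(is.na(report$pct_change), "-",
                        paste0(report$pct_change, "%")),
    value_total = ifelse(is.na(report$value_total), "-",
                         sprintf("%.2f", report$value_total)),
    stringsAsFactors = FALSE
  )
}

#' Compare a baseline report against alternative scenarios
#'
#' One row per (environment change, outcome) pair, one column of net annual
#' attributable cases per scenario; pairs inactive or absent in a scenario
#' render as a dash. A totals row is appended and explicitly flagged as not
#' adjusted for double counting (several pathways may affect the same people).
#'
#' @param baseline A `haus_report` for the baseline.
#' @param scenarios Named list of `haus_report`s (may be empty).
#' @return A `haus_comparison` data.frame (character cells, dash sentinel)
#'   with attribute `"note"` carrying the double-counting flag.
#' @export
compare_scenarios <- function(baseline, scenarios = list()) {
  all_reports <- c(list(Baseline = baseline), scenarios)
  if (is.null(names(all_reports)) || any(names(all_reports)[-1] == "")) {
    stop("aggregation error: scenarios must be named", call. = FALSE)
  }
  key_of <- function(r) paste(r$environment_change, r$outcome, sep = " | ")
  for (nm in names(all_reports)) {
    k <- key_of(all_reports[[nm]])
    if (anyDuplicated(k) > 0) {
      stop("aggregation error: duplicate (environment_change, outcome) key ",
           "in scenario '", nm, "': ", k[duplicated(k)][1], call. = FALSE)
    }
  }
  keys <- unique(unlist(lapply(all_reports, key_of)))
  first <- all_reports[[1]]
  out <- data.frame(
    environment_change = sub(" \\| .*$", "", keys),
    outcome = sub("^.* \\| ", "", keys),
    stringsAsFactors = FALSE
  )
  numeric_cols <- list()
  for (nm in names(all_reports)) {
    r <- all_reports[[nm]]
    m <- match(keys, key_of(r))
    vals <- r$attributable[m]            # NA when inactive or absent
    numeric_cols[[nm]] <- vals
    out[[nm]] <- format_count(vals)
  }
  totals <- data.frame(environment_change = "Total", outcome = "",
                       stringsAsFactors = FALSE)
  for (nm in names(numeric_cols)) {
    totals[[nm]] <- format_count(sum(numeric_cols[[nm]], na.rm = TRUE))
  }
  out <- rbind(out, totals)
  attr(out, "note") <-
    "Totals are not adjusted for double counting across pathways."
  class(out) <- c("haus_comparison", "data.frame")
  out
}

#' Re-run a scenario over a sweep of one exposure metric
#'
#' Overrides the named metric with each supplied value in turn and re-runs the
#' full evaluation, recomputing threshold activations each time. Useful for
#' locating the metric value at which a thresholded pathway switches on.
#'
#' @param scn A `haus_scenario` whose `metrics` contain `metric`.
#' @param metric Metric name to sweep.
#' @param values Non-empty numeric vector of metric values.
#' @param pathways,population,rates,unit_values As for [run_scenario()].
#' @return List of `list(value =, report =)` in input order.
#' @export
sensitivity_sweep <- function(scn, metric, values, pathways, population,
                              rates, unit_values) {
  if (is.null(scn$metrics[[metric]])) {
    stop("sweep validation error: metric '", metric, "' is not named in ",
         "scenario '", scn$name, "'", call. = FALSE)
  }
  if (length(values) == 0) {
    stop("sweep validation error: empty values list", call. = FALSE)
  }
  lapply(values, function(v) {
    s2 <- scn
    s2$metrics[[metric]] <- v
    list(value = v,
         report = run_scenario(s2, pathways, population, rates, unit_values))
  })
}

#' @export
print.haus_report <- function(x, ...) {
  cat("<haus_report> scenario '", attr(x, "scenario"), "': ", nrow(x),
      " pathway row(s), ", sum(x$active), " active\n", sep = "")
  print(format_report(x))
  invisible(x)
}

#' @export
print.haus_comparison <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  print(df)
  cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}
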