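# Project timelines with lagged onset of health effects, and monetization of
# attributable health impacts from the societal perspective (GBP 2019).

#' Construct a project timeline with a lag ramp
#'
#' Health effects of an environmental change phase in over a lag period: with
#' the default ramp only 20% of the full annual effect is realised in year 1,
#' 40% in year 2, and so on to 100% in year 5. Effects are only counted within
#' the project lifetime, capped by default at 25 years.
#'
#' @param T_intervention Project duration in whole years, >= 1.
#' @param lag_ramp Non-decreasing fractions in `(0, 1]` ending at 1; years
#'   beyond the ramp carry the full effect.
#' @param cap_years Maximum number of years over which effects are counted.
#' @return A `haus_timeline` list.
#' @export
project_timeline <- function(T_intervention = 25L,
                             lag_ramp = c(0.2, 0.4, 0.6, 0.8, 1.0),
                             cap_years = 25L) {
  T_intervention <- as.integer(T_intervention)
  cap_years <- as.integer(cap_years)
  if (is.na(T_intervention) || T_intervention < 1) {
    stop("timeline validation error: T_intervention must be >= 1", call. = FALSE)
  }
  if (is.na(cap_years) || cap_years < 1) {
    stop("timeline validation error: cap_years must be >= 1", call. = FALSE)
  }
  lag_ramp <- as.numeric(lag_ramp)
  if (length(lag_ramp) == 0 || any(lag_ramp <= 0 | lag_ramp > 1) ||
      is.unsorted(lag_ramp) || lag_ramp[length(lag_ramp)] != 1) {
    stop("timeline validation error: lag_ramp must be non-decreasing, in ",
         "(0, 1], and end at 1", call. = FALSE)
  }
  structure(
    list(T_intervention = T_intervention, lag_ramp = lag_ramp,
         cap_years = cap_years),
    class = "haus_timeline"
  )
}

#' Per-year effect fractions of a timeline
#'
#' The ramp fraction for each counted project year: the lag ramp for its first
#' years, then 1, truncated at `min(T_intervention, cap_years)` years.
#'
#' @param timeline A `haus_timeline`.
#' @return Numeric vector of fractions, one per counted year.
#' @export
ramp_fractions <- function(timeline) {
  stopifnot(inherits(timeline, "haus_timeline"))
  dur <- min(timeline$T_intervention, timeline$cap_years)
  full <- c(timeline$lag_ramp,
            rep(1, max(0, dur - length(timeline$lag_ramp))))
  full[seq_len(dur)]
}

#' Effective exposure-years of a project
#'
#' The sum of the per-year ramp fractions over the counted project years: the
#' number of full-effect years the project is equivalent to. With the default
#' ramp this is 0.2 for a 1-year project, 3.0 for 5 years, and `T - 2` for any
#' duration from 5 to the 25-year cap (23.0 at the cap).
#'
#' @param timeline A `haus_timeline`.
#' @return Dimensionless years-equivalent.
#' @export
effective_exposure_years <- function(timeline) {
  sum(ramp_fractions(timeline))
}

#' Project-lifetime total of an annual attributable effect
#'
#' Multiplies a constant annual attributable quantity (cases or deaths per
#' year) by the effective exposure-years of the timeline. Rates and risk
#' ratios are assumed constant over the project; the sign of the annual
#' effect is preserved.
#'
#' @param annual_attributed Annual attributable cases or deaths (may be
#'   negative).
#' @param timeline A `haus_timeline`.
#' @return Statistical cases or deaths over the project lifetime.
#' @export
total_effect <- function(annual_attributed, timeline) {
  if (!is.finite(annual_attributed)) {
    stop("timeline validation error: annual_attributed must be finite",
         call. = FALSE)
  }
  annual_attributed * effective_exposure_years(timeline)
}

# ---- unit values -----------------------------------------------------------

unit_value_columns <- c(
  "outcome_id", "per_case", "per_year", "vsl", "vsly",
  "comp_medical", "comp_productivity_informal", "comp_disutility",
  "share_individual", "share_employer", "share_healthcare", "share_state"
)

haus_components <- c("medical", "productivity_informal_care", "disutility")
haus_bearers <- c("individual_family", "employer", "healthcare_provider", "state")

#' Construct a unit-value table (GBP 2019, societal perspective)
#'
#' Per-outcome societal costs: per case and per year of ill health for
#' morbidity, and the value of a statistical life (VSL) / statistical life
#' year (VSLY) for mortality. Each outcome carries a cost-component breakdown
#' (medical; productivity and informal care; disutility, i.e. the monetised
#' pain-and-suffering WTP) that must sum to the per-case total within 0.5%,
#' and bearer shares (individual/family, employer, healthcare provider,
#' state) that must sum to 1.
#'
#' @param df data.frame with columns `outcome_id`, `per_case`, `per_year`,
#'   `vsl`, `vsly`, `comp_medical`, `comp_productivity_informal`,
#'   `comp_disutility`, `share_individual`, `share_employer`,
#'   `share_healthcare`, `share_state`.
#' @return A validated `haus_unit_values` data.frame.
#' @export
unit_value_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(unit_value_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("unit-value schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, unit_value_columns, drop = FALSE]
  df$outcome_id <- as.character(df$outcome_id)
  for (col in unit_value_columns[-1]) df[[col]] <- as.numeric(df[[col]])
  money <- c("per_case", "per_year", "vsl", "vsly", "comp_medical",
             "comp_productivity_informal", "comp_disutility")
  for (col in money) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop("unit-value validation error: negative ", col, call. = FALSE)
    }
  }
  comp_sum <- df$comp_medical + df$comp_productivity_informal + df$comp_disutility
  has_case <- !is.na(df$per_case) & df$per_case > 0 & !is.na(comp_sum)
  rel <- abs(comp_sum[has_case] - df$per_case[has_case]) / df$per_case[has_case]
  if (any(rel > 0.005)) {
    stop("unit-value validation error: cost components do not sum to per_case ",
         "within 0.5% for outcome(s): ",
         paste(df$outcome_id[has_case][rel > 0.005], collapse = ", "),
         call. = FALSE)
  }
  share_sum <- df$share_individual + df$share_employer + df$share_healthcare +
    df$share_state
  if (any(abs(share_sum - 1) > 1e-9)) {
    stop("unit-value validation error: bearer shares must sum to 1",
         call. = FALSE)
  }
  if (anyDuplicated(df$outcome_id) > 0) {
    stop("unit-value validation error: duplicate outcome_id", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("haus_unit_values", "data.frame")
  df
}

#' Read / write a unit-value CSV (GBP 2019)
#' @param path File path.
#' @return A `haus_unit_values`.
#' @export
read_unit_values <- function(path) {
  if (!file.exists(path)) {
    stop("unit-value load error: file not found: ", path, call. = FALSE)
  }
  unit_value_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}

#' @rdname read_unit_values
#' @param unit_values A `haus_unit_values` to write.
#' @export
write_unit_values <- function(unit_values, path) {
  write_csv_full_precision(as.data.frame(unit_values), path)
}

#' Monetize an attributable health quantity
#'
#' Multiplies an attributable quantity (project-lifetime cases, deaths or
#' life-years) by the requested unit rate and disaggregates the total three
#' ways: by project year (proportionally to the lag-ramp fractions, so money
#' follows cases), by cost component, and by cost bearer. Components are
#' applied as proportions of their own sum, bearers by their shares; all
#' breakdowns scale linearly and sum back to the total.
#'
#' @param quantity Attributable cases, deaths or years over the project
#'   lifetime (may be negative: a benefit).
#' @param unit_value One row of a `haus_unit_values` (or the whole table plus
#'   `outcome_id`).
#' @param basis One of `"per_case"`, `"per_year"`, `"vsl"`, `"vsly"`.
#' @param timeline A `haus_timeline` used to spread the total across years.
#' @param outcome_id Outcome key, required when `unit_value` has several rows.
#' @return A `haus_value` list: `outcome_id`, `basis`, `total`,
#'   `by_component`, `by_bearer`, `by_year`.
#' @export
monetize <- function(quantity, unit_value,
                     basis = c("per_case", "per_year", "vsl", "vsly"),
                     timeline = project_timeline(), outcome_id = NULL) {
  basis <- match.arg(basis)
  uv <- unit_value
  if (is.data.frame(uv) && nrow(uv) != 1) {
    if (is.null(outcome_id)) {
      stop("valuation error: outcome_id required with a multi-row unit-value ",
           "table", call. = FALSE)
    }
    uv <- uv[uv$outcome_id == outcome_id, , drop = FALSE]
    if (nrow(uv) != 1) {
      stop("valuation error: no unit value for outcome '", outcome_id, "'",
           call. = FALSE)
    }
  }
  uv <- as.list(uv)
  rate <- uv[[basis]]
  if (is.null(rate) || is.na(rate)) {
    stop("valuation error: basis '", basis, "' is not populated for outcome '",
         uv$outcome_id, "'", call. = FALSE)
  }
  total <- quantity * rate
  comps <- c(uv$comp_medical, uv$comp_productivity_informal, uv$comp_disutility)
  comp_frac <- if (all(!is.na(comps)) && sum(comps) > 0) comps / sum(comps)
               else c(0, 0, 1)  # valuation wholly disutility when unsplit
  shares <- c(uv$share_individual, uv$share_employer, uv$share_healthcare,
              uv$share_state)
  fr <- ramp_fractions(timeline)
  structure(
    list(
      outcome_id = uv$outcome_id,
      basis = basis,
      total = total,
      by_component = stats::setNames(total * comp_frac, haus_components),
      by_bearer = stats::setNames(total * shares, haus_bearers),
      by_year = total * fr / sum(fr)
    ),
    class = "haus_value"
  )
}

#' Present value of an annual money stream
#'
#' Standard geometric discounting from year 1:
#' `PV = sum_t by_year[t] / (1 + rate)^t`. A zero rate returns the
#' undiscounted sum exactly; the package default is no discounting.
#'
#' @param by_year Numeric vector of GBP per project year (may be empty).
#' @param rate Discount rate per year, >= 0.
#' @return Present value in GBP.
#' @export
discount_stream <- function(by_year, rate = 0) {
  if (!is.finite(rate) || rate < 0) {
    stop("valuation error: discount rate must be >= 0", call. = FALSE)
  }
  if (length(by_year) == 0) return(0)
  sum(by_year / (1 + rate)^seq_along(by_year))
}

#' @export
print.haus_value <- function(x, ...) {
  cat(sprintf("<valuation> outcome '%s' (basis %s): GBP %.2f over %d year(s)\n",
              x$outcome_id, x$basis, x$total, length(x$by_year)))
  invisible(x)
}

#' @export
print.haus_timeline <- function(x, ...) {
  cat(sprintf(paste0("<timeline> %d year(s), cap %d, ramp [%s] -> %.1f ",
                     "effective exposure-years\n"),
              x$T_intervention, x$cap_years,
              paste(x$lag_ramp, collapse = ", "),
              effective_exposure_years(x)))
  invisible(x)
}
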