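# Age-structured population profiles, baseline rate tables, and exposure
# partitioning. Persons and cases are statistical (fractional) quantities and
# are carried at full precision; rounding is a presentation concern.

#' Construct an age-structured population profile
#'
#' One row per single year of age, with the stratum count and the remaining
#' life expectancy at that age. Counts may be fractional (statistical
#' persons). An optional `male_fraction` per stratum (default 0.5) supports
#' sex-restricted pathway populations; the required CSV columns are
#' unaffected.
#'
#' @param age Integer ages in years (unique within a profile).
#' @param count Nonnegative stratum counts (persons; fractional allowed).
#' @param life_expectancy Positive remaining life expectancy in years.
#' @param male_fraction Fraction of each stratum that is male, in `[0, 1]`.
#' @param label Profile label used by scenarios to reference the profile.
#' @return A `haus_population` data.frame with attribute `label`.
#' @export
population_profile <- function(age, count, life_expectancy,
                               male_fraction = 0.5, label = "") {
  age <- as.numeric(age)
  count <- as.numeric(count)
  life_expectancy <- as.numeric(life_expectancy)
  n <- length(age)
  stopifnot(length(count) == n, length(life_expectancy) == n)
  male_fraction <- rep_len(as.numeric(male_fraction), n)
  if (anyDuplicated(age) > 0) {
    stop("population validation error: duplicate ages in profile", call. = FALSE)
  }
  if (any(count < 0)) {
    stop("population validation error: negative stratum count", call. = FALSE)
  }
  if (n > 0 && any(!is.finite(life_expectancy) | life_expectancy <= 0)) {
    stop("population validation error: life_expectancy must be > 0", call. = FALSE)
  }
  if (any(male_fraction < 0 | male_fraction > 1)) {
    stop("population validation error: male_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  df <- data.frame(age = age, count = count, life_expectancy = life_expectancy,
                   male_fraction = male_fraction)
  df <- df[order(df$age), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("haus_population", "data.frame")
  df
}

#' Total population of a profile
#' @param profile A `haus_population`.
#' @return Total persons (may be fractional).
#' @export
population_total <- function(profile) sum(profile$count)

#' Read / write a population profile CSV
#'
#' Columns: `age`, `count`, `life_expectancy` (one row per age year), plus an
#' optional `male_fraction` column. UTF-8 with header.
#'
#' @param path File path.
#' @param label Label to attach to the profile.
#' @return A `haus_population`.
#' @export
read_population <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    stop("population load error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("age", "count", "life_expectancy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("population schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mf <- if ("male_fraction" %in% names(df)) df$male_fraction else 0.5
  population_profile(df$age, df$count, df$life_expectancy, mf, label = label)
}

#' @rdname read_population
#' @param profile A `haus_population` to write.
#' @export
write_population <- function(profile, path) {
  write_csv_full_precision(as.data.frame(profile), path)
}

#' Select an age (and sex) band of a population
#'
#' Age bands are half-open `[age_min, age_max)` in integer years, so adjacent
#' bands partition a population without double counting. An empty band is not
#' an error here (it returns a profile with total 0); evaluating a pathway
#' against an empty profile fails downstream.
#'
#' @param profile A `haus_population`.
#' @param age_min,age_max Band limits in years, `age_min < age_max`.
#' @param sex Optional `"male"` or `"female"`: stratum counts are multiplied
#'   by `male_fraction` (or its complement).
#' @return A `haus_population` restricted to the band.
#' @export
select_subpopulation <- function(profile, age_min, age_max, sex = NULL) {
  if (!(age_min < age_max)) {
    stop("subpopulation error: require age_min < age_max", call. = FALSE)
  }
  keep <- profile$age >= age_min & profile$age < age_max
  out <- as.data.frame(profile)[keep, , drop = FALSE]
  if (!is.null(sex) && !is.na(sex)) {
    if (!(sex %in% c("male", "female"))) {
      stop("subpopulation error: sex must be 'male' or 'female'", call. = FALSE)
    }
    frac <- if (sex == "male") out$male_fraction else 1 - out$male_fraction
    out$count <- out$count * frac
  }
  rownames(out) <- NULL
  attr(out, "label") <- attr(profile, "label")
  class(out) <- c("haus_population", "data.frame")
  out
}

#' Count-weighted mean remaining life expectancy
#'
#' The average remaining years of life per person in the profile: each
#' stratum's life expectancy weighted by its count. Undefined (an error) for
#' an empty profile.
#'
#' @param profile A `haus_population` with total > 0.
#' @return Mean remaining life expectancy in years.
#' @export
mean_remaining_life <- function(profile) {
  n <- population_total(profile)
  if (!(n > 0)) {
    stop("evaluation error: mean remaining life is undefined for an empty ",
         "population", call. = FALSE)
  }
  sum(profile$count * profile$life_expectancy) / n
}

#' Partition a population into exposed and unexposed persons
#'
#' Splits `n` persons by the exposed proportion `Pe`: `ne = n * Pe` exposed and
#' `nu = n * (1 - Pe)` unexposed, with `ne + nu = n` exactly. Fractional
#' (statistical) persons are permitted.
#'
#' @param n Total persons, `n > 0`.
#' @param Pe Exposed proportion in `[0, 1]`.
#' @return A `haus_exposure_split` list with fields `n`, `ne`, `nu`, `Pe`, `Pu`.
#' @export
split_exposure <- function(n, Pe) {
  if (!is.finite(n) || n <= 0) {
    stop("exposure validation error: n must be > 0", call. = FALSE)
  }
  if (!is.finite(Pe) || Pe < 0 || Pe > 1) {
    stop("exposure validation error: Pe must lie in [0, 1]", call. = FALSE)
  }
  ne <- n * Pe
  nu <- n - ne
  # n is re-derived as ne + nu so the conservation invariant ne + nu == n
  # holds identically in floating point (the re-derivation differs from the
  # input by at most one ulp)
  structure(
    list(n = ne + nu, ne = ne, nu = nu, Pe = Pe, Pu = 1 - Pe),
    class = "haus_exposure_split"
  )
}

#' @export
print.haus_exposure_split <- function(x, ...) {
  cat(sprintf("<exposure split> n = %g (exposed %g, unexposed %g; Pe = %g)\n",
              x$n, x$ne, x$nu, x$Pe))
  invisible(x)
}

# ---- rate tables -----------------------------------------------------------

rate_columns <- c("outcome_id", "age_min", "age_max", "rate_kind",
                  "annual_rate", "duration_years")

#' Construct a baseline rate table
#'
#' Annual per-person event probabilities from the literature: incidence rates
#' for morbidity/behaviour outcomes and mortality rates for fatal outcomes,
#' by outcome and half-open age band, with the average illness duration
#' (years) for morbidity rows. Bands for a given outcome and kind must not
#' overlap.
#'
#' @param df data.frame with columns `outcome_id`, `age_min`, `age_max`,
#'   `rate_kind` (`"incidence"` or `"mortality"`), `annual_rate` in `[0, 1]`,
#'   `duration_years` (> 0 for morbidity rows, `NA` otherwise).
#' @return A validated `haus_rates` data.frame.
#' @export
rate_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(rate_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("rate schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, rate_columns, drop = FALSE]
  for (col in c("age_min", "age_max", "annual_rate", "duration_years")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$outcome_id <- as.character(df$outcome_id)
  df$rate_kind <- as.character(df$rate_kind)
  if (!all(df$rate_kind %in% c("incidence", "mortality"))) {
    stop("rate validation error: rate_kind must be 'incidence' or 'mortality'",
         call. = FALSE)
  }
  if (any(is.na(df$annual_rate) | df$annual_rate < 0 | df$annual_rate > 1)) {
    stop("rate validation error: annual_rate must lie in [0, 1]", call. = FALSE)
  }
  if (any(df$age_min >= df$age_max)) {
    stop("rate validation error: require age_min < age_max", call. = FALSE)
  }
  if (any(!is.na(df$duration_years) & df$duration_years <= 0)) {
    stop("rate validation error: duration_years must be > 0 where present",
         call. = FALSE)
  }
  # non-overlap within (outcome_id, rate_kind)
  key <- paste(df$outcome_id, df$rate_kind, sep = "\r")
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    rows <- rows[order(rows$age_min), , drop = FALSE]
    if (nrow(rows) > 1 &&
        any(rows$age_max[-nrow(rows)] > rows$age_min[-1])) {
      stop("rate schema error: overlapping age bands for outcome '",
           rows$outcome_id[1], "' (", rows$rate_kind[1], ")", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("haus_rates", "data.frame")
  df
}

#' Read / write a rate table CSV
#'
#' Columns: `outcome_id`, `age_min`, `age_max`, `rate_kind`, `annual_rate`,
#' `duration_years`. UTF-8 with header.
#'
#' @param path File path.
#' @return A `haus_rates`.
#' @export
read_rates <- function(path) {
  if (!file.exists(path)) {
    stop("rate load error: file not found: ", path, call. = FALSE)
  }
  rate_table(utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
}

#' @rdname read_rates
#' @param rates A `haus_rates` to write.
#' @export
write_rates <- function(rates, path) {
  write_csv_full_precision(as.data.frame(rates), path)
}

#' Look up the baseline annual rate for an outcome and age band
#'
#' Returns the literature rate (and, for morbidity, the illness duration) for
#' the requested half-open band. A band covered by a single rate row returns
#' that row's values directly. A band spanning several rows returns the
#' count-weighted average over the overlap, with weights taken from the
#' supplied population profile. A band not fully covered where population is
#' present raises a missing-rate error.
#'
#' @param rates A `haus_rates`.
#' @param outcome_id Outcome key.
#' @param age_band Numeric length-2 `(age_min, age_max)`, half-open.
#' @param rate_kind `"incidence"` or `"mortality"`.
#' @param profile A `haus_population`; required when the band spans more than
#'   one rate row (it provides the averaging weights).
#' @return List with `annual_rate` and `duration_years` (`NA` for mortality).
#' @export
lookup_rate <- function(rates, outcome_id, age_band,
                        rate_kind = c("incidence", "mortality"),
                        profile = NULL) {
  rate_kind <- match.arg(rate_kind)
  lo <- age_band[1]; hi <- age_band[2]
  stopifnot(lo < hi)
  rows <- rates[rates$outcome_id == outcome_id & rates$rate_kind == rate_kind, ,
                drop = FALSE]
  rows <- rows[rows$age_max > lo & rows$age_min < hi, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("missing-rate error: no ", rate_kind, " rate for outcome '",
         outcome_id, "' covering [", lo, ", ", hi, ")", call. = FALSE)
  }
  if (nrow(rows) == 1 && rows$age_min[1] <= lo && rows$age_max[1] >= hi) {
    return(list(annual_rate = rows$annual_rate[1],
                duration_years = rows$duration_years[1]))
  }
  if (is.null(profile)) {
    stop("missing-rate error: band [", lo, ", ", hi, ") for outcome '",
         outcome_id, "' spans multiple rate rows; a population profile is ",
         "required for count-weighted averaging", call. = FALSE)
  }
  band_pop <- select_subpopulation(profile, lo, hi)
  w <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    seg_lo <- max(lo, rows$age_min[i])
    seg_hi <- min(hi, rows$age_max[i])
    w[i] <- sum(band_pop$count[band_pop$age >= seg_lo & band_pop$age < seg_hi])
  }
  # uncovered sub-band containing population -> missing rate
  covered <- band_pop$age >= -Inf & Reduce(`|`, lapply(seq_len(nrow(rows)),
    function(i) band_pop$age >= rows$age_min[i] & band_pop$age < rows$age_max[i]))
  if (any(band_pop$count[!covered] > 0)) {
    stop("missing-rate error: band [", lo, ", ", hi, ") for outcome '",
         outcome_id, "' is not fully covered by the rate table", call. = FALSE)
  }
  if (sum(w) <= 0) {
    stop("missing-rate error: no population weight in band [", lo, ", ", hi,
         ") for outcome '", outcome_id, "'", call. = FALSE)
  }
  dur <- rows$duration_years
  list(
    annual_rate = sum(w * rows$annual_rate) / sum(w),
    duration_years = if (all(is.na(dur))) NA_real_
                     else sum(w * dur) / sum(w)
  )
}

#' @export
print.haus_population <- function(x, ...) {
  cat(sprintf("<haus_population> '%s': %d age strata, total %.6g persons\n",
              attr(x, "label"), nrow(x), population_total(x)))
  invisible(x)
}
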