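# Attributable-effect engine: odds-ratio-adjusted excess deaths and cases,
# statistical life-years lost (YLL) and years lived with illness (YLD), and a
# Monte-Carlo oracle that verifies the closed forms by simulation.
#
# Model: the exposed stratum's annual event probability is the literature rate
# multiplied by the pathway's odds ratio (rare-outcome OR ~ RR approximation,
# no odds-to-risk conversion); the unexposed stratum keeps the literature
# rate. The attributable annual effect is the excess of the exposure-adjusted
# total over the no-exposure expectation:
#   attributed = (exposed events + unexposed events) - expected events
#              = ne * rate * (OR - 1),
# which is negative for protective pathways (OR < 1).

clamp_rate <- function(rate, what) {
  if (rate > 1) {
    # overshoot within floating-point noise is clamped silently; a genuine
    # degenerate input (high OR on a common outcome) is clamped with a warning
    if (rate > 1 + 1e-9) {
      warning(what, " exceeds 1 (", format(rate), "); clamped to 1",
              call. = FALSE)
    }
    return(1)
  }
  rate
}

#' Attributable deaths from one mortality pathway
#'
#' Given an exposure split of the assessed population, the literature annual
#' mortality rate `MRlit` and the pathway odds ratio `OR`, computes the
#' exposed-stratum rate `MRe = MRlit * OR` (clamped to 1 with a warning if it
#' exceeds 1), annual deaths in each stratum, the expected deaths without the
#' exposure, and the attributable excess
#' `Dattributed = (De + Du) - Dexpected = ne * MRlit * (OR - 1)`.
#' All counts are statistical deaths per year and may be fractional;
#' `Dattributed` is negative when the pathway is protective.
#'
#' @param split A `haus_exposure_split` from [split_exposure()].
#' @param MRlit Annual mortality probability in `[0, 1]`.
#' @param OR Odds ratio, > 0.
#' @return A `haus_mortality` list: `MRe`, `MRu`, `De`, `Du`, `Dexpected`,
#'   `Dattributed`, plus `YLLe`, `YLLu`, `YLLattributed` (`NA` until
#'   [attributable_yll()] populates them).
#' @export
attributable_deaths <- function(split, MRlit, OR) {
  stopifnot(inherits(split, "haus_exposure_split"))
  if (!is.finite(MRlit) || MRlit < 0 || MRlit > 1) {
    stop("engine validation error: MRlit must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(OR) || OR <= 0) {
    stop("engine validation error: OR must be > 0", call. = FALSE)
  }
  MRu <- MRlit
  MRe <- clamp_rate(MRlit * OR, "exposed mortality rate MRlit * OR")
  De <- MRe * split$ne
  Du <- MRu * split$nu
  Dexpected <- MRlit * split$n
  structure(
    list(MRe = MRe, MRu = MRu, De = De, Du = Du, Dexpected = Dexpected,
         Dattributed = (De + Du) - Dexpected,
         YLLe = NA_real_, YLLu = NA_real_, YLLattributed = NA_real_),
    class = "haus_mortality"
  )
}

#' Attributable years of life lost
#'
#' Converts attributable deaths into statistical life-years lost using the
#' count-weighted mean remaining life expectancy of the affected population:
#' `YLLattributed = mean_LY * Dattributed`. The per-stratum totals
#' `YLLe = mean_LY * De` and `YLLu = mean_LY * Du` are reported for
#' transparency.
#'
#' @param result A `haus_mortality` from [attributable_deaths()].
#' @param mean_LY Mean remaining life expectancy in years, > 0
#'   (see [mean_remaining_life()]).
#' @return The `haus_mortality` with the YLL fields populated.
#' @export
attributable_yll <- function(result, mean_LY) {
  stopifnot(inherits(result, "haus_mortality"))
  if (!is.finite(mean_LY) || mean_LY <= 0) {
    stop("engine validation error: mean_LY must be > 0", call. = FALSE)
  }
  result$YLLe <- mean_LY * result$De
  result$YLLu <- mean_LY * result$Du
  result$YLLattributed <- mean_LY * result$Dattributed
  result
}

#' Attributable cases of illness from one morbidity pathway
#'
#' Morbidity analogue of [attributable_deaths()]: `IRe = IRlit * OR` (clamped
#' to 1 with a warning), `Ce = ne * IRe`, `Cu = nu * IRlit`,
#' `Cexpected = n * IRlit`, and
#' `Cattributed = (Ce + Cu) - Cexpected = ne * IRlit * (OR - 1)`.
#'
#' @param split A `haus_exposure_split`.
#' @param IRlit Annual incidence probability in `[0, 1]`.
#' @param OR Odds ratio, > 0.
#' @return A `haus_morbidity` list: `IRe`, `IRu`, `Ce`, `Cu`, `Cexpected`,
#'   `Cattributed`, plus `YLD` and `YLDattributed` (`NA` until
#'   [attributable_yld()] is applied).
#' @export
attributable_cases <- function(split, IRlit, OR) {
  stopifnot(inherits(split, "haus_exposure_split"))
  if (!is.finite(IRlit) || IRlit < 0 || IRlit > 1) {
    stop("engine validation error: IRlit must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(OR) || OR <= 0) {
    stop("engine validation error: OR must be > 0", call. = FALSE)
  }
  IRu <- IRlit
  IRe <- clamp_rate(IRlit * OR, "exposed incidence rate IRlit * OR")
  Ce <- IRe * split$ne
  Cu <- IRu * split$nu
  Cexpected <- IRlit * split$n
  structure(
    list(IRe = IRe, IRu = IRu, Ce = Ce, Cu = Cu, Cexpected = Cexpected,
         Cattributed = (Ce + Cu) - Cexpected,
         YLD = NA_real_, YLDattributed = NA_real_),
    class = "haus_morbidity"
  )
}

#' Per-case years lived with illness, capped by life expectancy
#'
#' The expected years of illness per case: the illness duration `Tsick` capped
#' at each stratum's remaining life expectancy (a case cannot outlast the
#' remaining lifetime of the individual), then count-weighted averaged over
#' the affected population. The cap is applied per stratum, before averaging.
#'
#' @param Tsick Average illness duration in years, > 0.
#' @param affected_profile A `haus_population` with total > 0.
#' @return Years per case.
#' @export
yld_per_case <- function(Tsick, affected_profile) {
  if (!is.finite(Tsick) || Tsick <= 0) {
    stop("engine validation error: Tsick must be > 0", call. = FALSE)
  }
  n <- population_total(affected_profile)
  if (!(n > 0)) {
    stop("evaluation error: YLD per case is undefined for an empty population",
         call. = FALSE)
  }
  sum(affected_profile$count *
        pmin(Tsick, affected_profile$life_expectancy)) / n
}

#' Attributable years lived with illness
#'
#' `YLDattributed = Cattributed * yld_per_case(Tsick, affected_profile)`.
#' Negative attributable cases (protective pathways) yield negative years,
#' i.e. years of illness averted.
#'
#' @param Cattributed Attributable cases per year (statistical, may be
#'   negative).
#' @param Tsick Average illness duration in years, > 0.
#' @param affected_profile A `haus_population` with total > 0.
#' @return Statistical years lived with illness per year of exposure.
#' @export
attributable_yld <- function(Cattributed, Tsick, affected_profile) {
  Cattributed * yld_per_case(Tsick, affected_profile)
}

#' Monte-Carlo oracle for the attributable-count closed forms
#'
#' Independent verification of the closed-form arithmetic by person-level
#' simulation: per replicate, each of the `ne` exposed persons experiences the
#' event with probability `min(rate * OR, 1)` and each of the `nu` unexposed
#' persons with probability `rate`; the replicate's attributed count is the
#' total events minus the no-exposure expectation `n * rate`. Returns the mean
#' and standard error over replicates. The oracle operates on whole persons
#' and is reproducible under a fixed seed.
#'
#' @param split A `haus_exposure_split` with integer `ne` and `nu`.
#' @param rate Annual event probability in `[0, 1]`.
#' @param OR Odds ratio, > 0.
#' @param reps Number of replicates, >= 1.
#' @param seed Integer RNG seed.
#' @return List with `mean` and `se` of the attributed count.
#' @export
mc_oracle <- function(split, rate, OR, reps = 1000L, seed = 1L) {
  stopifnot(inherits(split, "haus_exposure_split"))
  if (split$ne != round(split$ne) || split$nu != round(split$nu)) {
    stop("oracle validation error: the Monte-Carlo oracle needs whole-person ",
         "ne and nu", call. = FALSE)
  }
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    stop("oracle validation error: rate must lie in [0, 1]", call. = FALSE)
  }
  if (reps < 1) {
    stop("oracle validation error: reps must be >= 1", call. = FALSE)
  }
  pe <- min(rate * OR, 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  events <- stats::rbinom(reps, size = as.integer(split$ne), prob = pe) +
    stats::rbinom(reps, size = as.integer(split$nu), prob = rate)
  attributed <- events - split$n * rate
  list(
    mean = mean(attributed),
    se = if (reps > 1) stats::sd(attributed) / sqrt(reps) else NA_real_
  )
}

#' @export
print.haus_mortality <- function(x, ...) {
  cat(sprintf(paste0("<mortality result> MRe=%.6g MRu=%.6g | De=%.6g Du=%.6g ",
                     "expected=%.6g attributed=%.6g | YLLattributed=%.6g\n"),
              x$MRe, x$MRu, x$De, x$Du, x$Dexpected, x$Dattributed,
              x$YLLattributed))
  invisible(x)
}

#' @export
print.haus_morbidity <- function(x, ...) {
  cat(sprintf(paste0("<morbidity result> IRe=%.6g IRu=%.6g | Ce=%.6g Cu=%.6g ",
                     "expected=%.6g attributed=%.6g | YLDattributed=%.6g\n"),
              x$IRe, x$IRu, x$Ce, x$Cu, x$Cexpected, x$Cattributed,
              x$YLDattributed))
  invisible(x)
}
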