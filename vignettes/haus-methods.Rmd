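---
title: "Methods: impact-pathway health appraisal in haus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impact-pathway health appraisal in haus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haus)
```

## The model and its assumptions

`haus` estimates the health consequences of a change in the urban
environment by chaining **impact pathways**: documented dose–response links
from one environmental characteristic to one health outcome, each carrying
a point-estimate odds ratio `OR` for the exposed population. The engine
makes four structural assumptions, stated here explicitly because every
downstream number inherits them:

1. **OR as rate ratio.** The odds ratio multiplies the literature annual
   event probability directly (`Re = R·OR`), the standard rare-outcome
   approximation. No odds-to-risk conversion is applied; for common
   outcomes (e.g. "being active", baseline probability ≈ 0.6) this is a
   recognised distortion and products exceeding 1 are clamped to 1 with a
   warning. We deliberately keep the literal multiplicative form because
   the whole framework is linear and its outputs are approximations of
   scale, not forecasts.
2. **Attributable = exposure-adjusted minus expected.** The annual
   attributable count is `A = ne·R·(OR − 1)`: the excess of the
   exposure-adjusted total `(Ee + Eu)` over the no-exposure expectation
   `n·R`. This is the only form consistent with protective pathways
   producing negative attributable counts, and the YLL analogue is kept
   internally consistent as `YLL = LȲ·A` rather than a difference of
   stratum YLLs. Intermediate quantities (`Ee`, `Eu`, `Eexpected`, and the
   stratum rates) are reported on the result objects for transparency.
3. **Statistical persons.** Counts, cases and deaths are sums of many small
   risks, carried as fractional quantities at full precision. Rounding
   (integers for magnitudes ≥ 1, two decimals below 1, dash for
   inactive/undefined) happens only at presentation time, in
   `format_report()`.
4. **Stationarity.** Rates, odds ratios and demographics are held constant
   over the project lifetime; accumulation over time is a linear
   multiplier (below). No competing risks, no age drift, no uncertainty
   intervals on OR (point estimates only).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `lag_ramp` | fraction of full effect | 0.2, 0.4, 0.6, 0.8, 1.0 | five-year phase-in of health effects after an environmental change |
| `cap_years` | years | 25 | only effects within the project lifetime are counted |
| `T_intervention` | years | 25 | appraisal horizon of the packaged case study |
| `Pe` | proportion exposed | per scenario | exposure is a scenario input, not derived by the package |
| `Tsick` | years per case | per outcome | illness duration, capped per stratum at remaining life expectancy |
| discount rate | per year | 0 | the reference arithmetic is undiscounted; `discount_stream()` is available but off by default |
| currency | GBP 2019 | fixed | unit values are estimated for 2019; no indexation machinery |

With the default ramp, `effective_exposure_years(T) = T − 2` for
`5 ≤ T ≤ 25`, hence 23 effective years for a 25-year project. The ramp is
also applied to valuation streams (`monetize()` spreads money across years
proportionally to the ramp), so money follows cases; this is an
interpretive choice — the reference arithmetic only defines lifetime sums —
but it keeps cases and value consistent year by year.

## Age bands, rates and sex

Age bands are half-open `[min, max)` in integer years; population labels
like "Adults >18" map to `[18, ∞)` and "Children 9–12" to `[9, 13)`.
Half-open bands compose without double counting, which the partition
property tests rely on. Rates are annual per-person probabilities (not
hazards). When a requested band spans several rate rows, `lookup_rate()`
returns the count-weighted average over the overlap, weighted by the
population profile — this is also how the packaged case study keeps two
overlapping diabetes target populations consistent with a non-overlapping
rate table.

The population CSV schema is `age, count, life_expectancy` with an
**optional** `male_fraction` column (default 0.5). The pathway schema
supports sex-restricted target populations ("Men >18"); without a sex
dimension in the profile those pathways could not be evaluated, so the
optional column extends the contract without breaking the documented one.

## Valuation

Valuation is societal: per-case and per-year-of-illness unit costs for
morbidity, VSL and VSLY for mortality, all GBP 2019. The default bases are
`per_case × lifetime attributable cases` for morbidity and
`vsly × lifetime attributable YLL` for mortality (YLL is the finer-grained
mortality quantity; `vsl × deaths` and `per_year × YLD` are available via
`basis=`). Each total is disaggregated by cost component (medical;
productivity and informal care; disutility) and by bearer
(individual/family, employer, healthcare provider, state). Components are
stated against the per-case total, so for other bases they are applied as
proportions of their own sum; bearer shares must sum to 1 and breakdowns
always re-sum to the total (conservation is property-tested).

## What the synthetic data does and does not establish

The package contains no third-party evidence library. Two generators stand
in for it:

* `generate_pathway_library()` draws schema-valid pathways across all six
  typologies with log-uniform odds ratios (default range 0.5–2.5, 35%
  protective, 15% thresholded — chosen as representative magnitudes for
  urban-health dose–response estimates). It exercises validation, I/O and
  filtering, not epidemiology.
* `frome_gateway_fixture()` is a **back-solved** case study: the published
  summary tables of a real riverside regeneration appraisal (population
  9,241; subgroup sizes 6,927 / 3,262 / 3,616 / 588 / 583 / 1,223; 2.37 ha
  of green space; a 0.7 ha open-space threshold; four scenarios) are
  treated as ground truth, and the unpublished inputs — odds ratios,
  incidence rates, exposed proportions, unit values — are solved so the
  full engine reproduces each (expected, attributable) pair. Exposed
  proportions are round fractions (1 for site-wide proximity/NDVI
  pathways, 0.5 for park-use and sex-restricted pathways); the one
  exception, the park-use → weight-gain proportion rising to `0.5·139/127`
  in future scenarios, is itself back-solved from the published −127 →
  −139 change. The diabetes per-case value (£22.7m / 230 lifetime cases ≈
  £98.7k) and the VSLY (£41.5m / 680 life-years ≈ £61k) are back-solved
  from the two published lifetime-value anecdotes and land at credible UK
  magnitudes, which is reassuring but not evidence.

A green test against this fixture therefore establishes that the engine's
arithmetic, threshold logic, rounding and reporting reproduce the
published appraisal **given** its published summary numbers — it does not
validate the underlying epidemiology, the exposure assessment, or the
value-transfer estimates, none of which are in scope.

Two published inconsistencies are preserved deliberately: the child-asthma
proximity row prints 8 expected, 5 attributable, "60%" — irreproducible
under integer inputs (5/8 = 62.5%) — so the fixture back-solves to 4.8
attributable cases/yr, which renders as "5" and rounds to the printed 60%;
and the park-use → diabetes column is constant at −3 across scenarios even
though park use rises, so its exposed proportion is held fixed while the
weight-gain pathway's rises (the source tables are inconsistent here; the
fixture follows what they print).

## Numerical choices

* **Percent rounding** is half-away-from-zero to integer percent
  (reproduces −15, −13, 61, 39, 27 from the reference tables; R's
  `round()` half-to-even would not). Zero expected cases yields the dash
  sentinel, not a division error.
* **Clamping**: `R·OR > 1` is clamped to 1; overshoot within `1e-9`
  (floating-point noise from back-solved reciprocal pairs like
  `(463/588)·(588/463)`) is clamped silently, anything larger warns.
* **Exact conservation**: `split_exposure()` re-derives `n` as `ne + nu`
  so the conservation invariant holds identically in floating point (the
  re-derived total differs from the input by at most one ulp).
* **Determinism**: the pipeline is RNG-free; the Monte-Carlo oracle and
  the fixture generators take explicit seeds and restore the caller's RNG
  state. Reports are formatted with fixed rules, so identical inputs give
  byte-identical CSVs. Manifests contain input digests but no timestamps.
* **Degenerate inputs**: empty age bands are legal selections but
  evaluating a pathway against an empty subpopulation is an error; an
  empty pathway file is a warning, not an error.

## Open design decisions taken

* A pathway carries at most one `(comparator, value)` threshold against one
  named metric; compound activation conditions are out of scope.
* Pathways sharing an outcome are evaluated independently; comparison
  totals are explicitly flagged as not adjusted for double counting.
* The scenario comparison table reports net attributable cases per
  scenario (identical values repeat across scenarios for unchanged
  pathways), not scenario-minus-baseline differences.
* A dash in reports means "not applicable" (inactive pathway or undefined
  percent), never zero.
* The published headline scenario values (£3.5m / £28m / £5.4m) depend on
  unpublished unit values across all thirteen pathways and are not
  reproduced or asserted; only the two per-pathway anecdotes above are
  wired into the fixture.

## Known limitations

Linear dose–response only; no overlap adjustment between pathways; no
uncertainty propagation; exposure proportions are user inputs rather than
modelled from survey data; the OR-as-rate-ratio approximation degrades for
common outcomes; unit values are point estimates in a fixed price year.
These mirror the scope of the spreadsheet-based appraisal practice the
package serves, where results are read as orders of magnitude for option
comparison, not as predictions.
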