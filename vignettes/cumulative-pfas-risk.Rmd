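---
title: "Cumulative dietary PFAS risk in PFOA equivalents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative dietary PFAS risk in PFOA equivalents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixpeq)
```

## The problem and the model

Food almost never contains a single per- or polyfluoroalkyl substance
(PFAS); monitoring programmes find mixtures of legacy compounds (PFOS,
PFOA) and their shorter- and longer-chain homologues. Health-based guidance
exists for only a few of them — EFSA's 2020 group Tolerable Weekly Intake
(TWI) of 4.4 ng/kg bw per week covers PFOA, PFNA, PFOS and PFHxS — so a
single-compound assessment ignores most of the mixture.

`mixpeq` implements a cumulative assessment under **dose addition** using
**Relative Potency Factors** (RPFs): each compound's concentration is
scaled by its potency relative to the index compound PFOA (RPF = 1),
derived from liver-hypertrophy benchmark doses in rodents. The scaled
intakes are summed into PFOA equivalents (PEQ) and compared with the TWI.

For one food category the potency-weighted Estimated Weekly Intake is

$$
\mathrm{PEQ\text{-}EWI}_{FC}
 = \sum_{i=1}^{n} C_i \times RPF_i \times
   \frac{\mathrm{consumption}}{BW} \times 7,
$$

with $C_i$ the mean concentration of compound $i$ in the category (ng/kg
food), consumption the group's mean daily intake of the category
(stored in g/day, converted to kg/day inside `weekly_intake_term()`), $BW$
the standard body weight (kg) and 7 the day-to-week factor. Setting every
$RPF_i = 1$ gives the unweighted **concentration-based** (CB) comparator.
Category intakes sum to a total EWI per consumer group (`total_ewi()`),
which divided by the TWI gives the **Hazard Index** (`hazard_index()`);
HI > 1 flags potential concern. Each intake can also be expressed as a
percentage of the TWI (`pct_twi()`).

Several data-poor compounds carry an RPF *range* from read-across between
chain-length neighbours (PFHpS 0.6–2, PFPeS 0.001–0.6, PFTrDA 0.3–3; PFDA
4–10 and PFHpA 0–1 are also ranged). Scenarios are propagated
*coherently*: `scenario = "min"` puts every ranged compound at its minimum
simultaneously, `"max"` at its maximum. Per-compound mixed scenarios are
not enumerated — the published results the package reproduces report
exactly these two envelope scenarios, and the envelope brackets every
mixed combination anyway because the model is linear in each RPF.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| TWI | 4.4 | ng/kg bw/week | EFSA 2020 group TWI; overridable in `build_exposure_table(twi = )` for sensitivity analyses |
| body weights | 12 / 45 / 70 / 70 | kg | EFSA standard weights for toddlers / adolescents / adults / elderly |
| consumption | shipped grid | g/day | survey-weighted European means for the four animal-derived categories |
| RPF table | shipped grid | — | liver-hypertrophy RPFs incl. read-across ranges |
| occurrence bound | LB | — | the realistic estimate with ~92% censoring; UB available |

**The PFPeA potency.** The published RPF grid prints 0 for PFPeA, yet the
assessment's milk results carry a nonzero PFPeA intake consistent with the
hepatic reference point of 0.03 quoted in its discussion. The default table
ships 0.03 (which reproduces the published milk rows);
`default_rpf_table(pfpea_rpf = "literal")` restores the printed 0. Compounds
with RPF = 0 (PFBS, PFHxA, and PFHpA at the minimum) stay in the data
model: they contribute nothing to the PEQ path but their concentrations
still feed the CB path.

Compounds with an RPF but no occurrence record contribute nothing and are
never imputed. An occurrence compound with *no* RPF is a configuration
error unless explicitly skip-listed, in which case it is dropped with a
warning — silently losing mass from a cumulative assessment would bias it
low.

## Left-censored occurrence data

Monitoring results are ~92% left-censored (below LOD/LOQ). `bound_mean()`
implements pure substitution, the convention of the source assessment:
censored records contribute 0 under the lower bound (LB) and their
quantification limit under the upper bound (UB). When both LOD and LOQ are
reported, UB uses the LOQ — it is the reporting limit in European datasets
and the conservative larger bound. No distributional imputation
(Kaplan–Meier, regression on order statistics) is offered: the reproduced
assessment uses substitution, and mixing estimators would break
comparability. A consequence worth stating: LB means are driven entirely
by the small quantifiable tail, so a handful of highly contaminated
samples dominates the average — the package's censoring-dominance tests
assert exactly this behaviour.

Survey-weighted consumption (`weighted_mean_consumption()`) takes explicit
weights; subject counts are the intended weighting variable, but the
column is user-supplied input rather than something the package infers.

## What the synthetic generator emulates — and what it does not

`generate_occurrence_samples()` draws, per compound × category stratum,
records censored with probability `censor_prob` (default 0.92) and
quantified concentrations from a lognormal law — heavy-tailed, so that
occasional high outliers drive the mean, matching the structure of the
real monitoring data. `analytic_lb_mean()` gives the closed-form expected
LB mean, $(1-p)\,e^{\mu+\sigma^2/2}$, used by the recovery tests: at
$n = 10^4$ records the empirical LB mean must sit within 3 Monte-Carlo
standard errors of it and the censored fraction within the binomial 99%
interval. The default multi-stratum design
(`default_synthetic_truth()`) covers the 16 compounds observed in the
reference occurrence data across the four categories, with higher medians
for the dominant legacy compounds.

The generator emulates *structure*, not *values*: strata are independent
(the source data give no within-sample compound correlations), limits are
fixed per stratum rather than laboratory-specific, and concentrations are
stationary. Passing recovery tests therefore demonstrates that the
estimator chain (substitution → intake → cumulation → HI) is correct under
the assumed data-generating process, not that real European occurrence
levels are reproduced.

## Rounding and reporting

All computation is at full floating precision; rounding happens once, in
the report layer. Intakes and hazard indices print with two decimals, %TWI
as whole percentages, ties rounded **half away from zero** — the mode
inferred from the reproduced tables, where a cumulative egg intake of 3.85
(i.e. 87.5% of 4.4) prints as 88%. R's default round-half-to-even would
send such ties toward the even digit, so the package implements the
away-from-zero rule explicitly (`round_half_away()`), with a one-ulp guard
so decimal ties stored just below .5 in binary still round up. Percentages are computed from
*unrounded* intakes, never from displayed values: the reproduced tables
round components and cumulatives independently from full precision, which
is why a printed row of components can differ from its printed cumulative
by ±0.01–0.02. A rendered `"0.00"` means below display precision, never
absent.

## Numerical and degenerate-input choices

* An empty set of intake terms cumulates to 0 with a warning, not an
  error: a category can legitimately lack occurrence records.
* `cumulative_ewi()` refuses to sum across mixed categories, groups, modes
  or scenarios — silent cross-stratum sums are the classic aggregation bug.
* The engine is fully vectorised but is tested against a naive per-record
  loop oracle at 1e-12 relative tolerance, and is deterministic:
  identical inputs give bit-identical outputs.
* `back_derive_concentration()` inverts the intake equation for
  diagnostics; inversion with RPF = 0 or zero consumption is refused as
  non-invertible rather than returning `Inf`.

## Reference fixtures

The package ships verbatim transcriptions of the published assessment's
printed tables (consumption grid, RPF grid, per-compound and cumulative
PEQ intakes, totals and hazard indices) under
`inst/extdata/reference/`. `validate_reference_tables()` checks their
internal identities — category cumulatives sum exactly to group totals,
printed HIs equal totals / 4.4 rounded to two decimals, the toddler milk
row sums exactly to its cumulative, other rows within ±0.02 of independent
component rounding. One transcription choice: the published egg table
duplicates a PFHpA/PFUnDA column block; the fixture keeps the first
instance of each compound, which reproduces the printed cumulative
exactly. These tables are frozen: they are validation targets, never
regenerated.

Problem sizes used by the test and acceptance runs — 10^4 synthetic
records per recovery check, ≤ 1000-record tables for oracle equivalence —
were chosen as the smallest sizes at which the Monte-Carlo bands are tight
enough to be informative.

## Known limitations

* Group-specific EWIs are treated independently; published intakes across
  groups do not scale exactly as consumption/BW ratios (the upstream data
  appear to use group-specific occurrence subsets), so no cross-group
  identity is asserted or exploited.
* Only the four flat animal-derived categories are modelled; no FoodEx2
  hierarchy, recipe decomposition, or non-animal sources (which the source
  opinion flags as additional contributors).
* RPFs are taken as given for a hepatic endpoint, while the TWI rests on
  immunotoxicity; the comparison is the published assessment's choice and
  inherits its caveats.
* The UB scenario is supported end to end but has no published headline to
  validate against; LB is the validated path.

## A worked example

```{r example}
# back-derive the adult fish PFOS concentration from its published intake,
# then run the full engine forward
conc <- back_derive_concentration(7.72, rpf = 2, consumption = 25.6,
                                  body_weight = 70)
occ <- tibble::tibble(compound = "PFOS", food_category = "fish_seafood",
                      mean_lb = conc, mean_ub = NA_real_)
risk <- suppressWarnings(
  build_exposure_table(occ, groups = "adults"))
risk$totals
```
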