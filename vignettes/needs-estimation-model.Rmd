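---
title: "The needs-estimation model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The needs-estimation model: assumptions, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palneed)
```

# The model

`palneed` is a deterministic accounting pipeline, not a statistical
estimator: every output is an exact arithmetic function of its input
tables. The chain has four stages.

**Need.** For each country and each of the 20 serious-illness conditions,
people in need of palliative care are

$$N_{dec}(c) = D(c)\,f_{dec}(c), \qquad N_{nondec}(c) = P(c)\,f_{nondec}(c),$$

where $D(c)$ is decedent deaths, $P(c)$ prevalent non-fatal cases, and
$f_{dec}, f_{nondec} \in [0,1]$ the need fractions — the proportions of each
population experiencing moderate or severe physical or psychological
suffering requiring palliation. Fractional persons are retained throughout;
nothing is rounded until a report table is written. The model is linear and
monotone in the caseload by construction, which is what the property suite
verifies.

**Symptom-days.** With prevalence $p(c,s,m)$ and mean duration $d(c,s,m)$
(days) for symptom $s$ under status $m \in \{\text{decedent},
\text{non-decedent}\}$, the two bounds are

$$\text{at-most} = \sum_{c,m,s} N(c,m)\,p(c,s,m)\,d(c,s,m), \qquad
  \text{at-least} = \sum_{c,m} N(c,m)\,p(c,s^*,m)\,d(c,s^*,m),$$

where $s^*$ is the longest-duration symptom for $(c,m)$. The upper bound
counts every symptom's days as if none overlapped; the lower bound assumes
all shorter symptoms run concurrently inside the longest one. Reality lies
between; the package makes no attempt to model day-level overlap.

**Opioid access.** DOME (distributed-opioid oral morphine equivalents) is
$\sum q_i \cdot e_i$ over non-methadone supply records, with $e_i$ the
equianalgesic factor (mg oral morphine per mg product). Methadone is
excluded by definition of the measure — its long, variable half-life makes
simple equianalgesic conversion unreliable. The modelled requirement prices
pain-days and terminal-dyspnea-days at fixed daily doses; percent of need
met is the uncapped ratio of the two, so values above 100% are meaningful
(supply exceeding the modelled palliative requirement, e.g. where
procedural use is large).

**Workforce.** Patients in need × per-patient encounter coefficients give
inpatient days and outpatient visits at four facility levels plus home
visits; hours-per-encounter staffing norms divided by annual FTE hours give
FTEs per category and level. Everything is additive over conditions,
levels, and countries, so the regional total always equals the total of
income-group subtotals.

# Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| need fractions $f_{dec}, f_{nondec}$ | proportion | per condition, see `pc_conditions()` | planning assumptions; the stated framework values are sparse, so defaults are explicit and editable |
| symptom prevalence/duration | proportion, days | `make_default_coefficients()` | all framework-stated cells exact (cancer-decedent pain 0.80 × 90 d; dyspnea 1.00 lung, 0.775 heart, 0.70 HIV, 0.50 liver and prematurity); the rest are flagged placeholders |
| pain daily dose | mg OME/day | 67.5 | a basic effective oral morphine dose for moderate/severe pain (midpoint-style planning figure) |
| terminal-dyspnea daily dose | mg OME/day | 10 | low-dose opioid titration typical for refractory dyspnea |
| equianalgesic factors | mg OME/mg | morphine 1 (oral) / 3 (parenteral), oxycodone 1.5, hydromorphone 4, fentanyl TD 100 | standard conversion-table values; fully overridable per scenario |
| `requirement_population` | — | `"all"` | whether non-decedent pain-days enter the requirement; decedents-only available as a switch |
| `at_least_weighting` | — | `"prevalence"` | see below |
| encounter base rates | days, visits / patient | decedent 12 ip / 8 op / 30 home; non-decedent 3 / 10 / 15 | essential-package utilisation planning figures |
| level allocation | share | referral .40/.18, provincial .27/.15, district .32/.33, CHC .01/.34 (inpatient/outpatient) | follows the facility mix of published essential-package workforce estimates |
| staffing norms | hours/encounter | `default_staffing_norms()` | calibrated so a country with need ≈ 0.4% of population yields densities of the order of 1–2 doctor, 2–4 nurse, 5–11 CHW FTEs per 100,000 |
| annual FTE hours | hours/year | 1650 | a standard full-time planning figure |

# Design choices where the design was open

**The at-least bound is prevalence-weighted.** The natural reading of the
two bounds weights both by prevalence; an alternative assumes the longest
symptom affects every person in need (prevalence 1). The package defaults
to prevalence weighting — consistent with the upper bound's treatment and
never exceeding it cell-wise — and exposes `at_least_weighting = "unit"`
for the other reading. Duration ties break toward the higher prevalence,
then the lexicographically first symptom label, making the bound
deterministic under permutation of the coefficient table.

**Requirement population.** Whether non-decedent pain-days belong in the
opioid requirement is genuinely ambiguous; both populations suffer pain,
so the default includes both (`requirement_population = "all"`), with a
decedents-only switch. Terminal dyspnea is always decedents-only: "terminal"
ties it to end-of-life care.

**One encounter-coefficient table per scenario.** Encounter coefficients
are keyed by (condition, status, level) and shared across countries; the
per-income-group level-allocation profiles are a generator input used to
build that table (the default build uses the middle-income profile) and
are carried in the scenario so users can rebuild per-group tables with
`build_encounter_coefficients()`. Keying coefficients by income group as
well would multiply the table fourfold for detail the default profiles do
not actually vary.

**No correction for procedural opioid use.** DOME includes surgical and
procedural consumption, which inflates apparent palliative access. The
accounting deliberately matches that definition; `procedural_fraction` in
the requirement parameters is a sensitivity hook, default 0.

**Rounding.** Report tables round half-up — counts to thousands, symptom
days to millions, FTEs to integers, densities to 2 decimals — and totals
are computed from unrounded values, then rounded. This is why a reported
total row can sit one unit off the sum of its printed entries; the package
reproduces the unrounded-summation convention and documents, rather than
reproduces, such off-by-one artifacts. `round_half_up()` applies a
4-ulp relative nudge before flooring so that values stored fractionally
below a representable half (e.g. 1.85 read back from text) still round as
printed.

**Degenerate inputs.** Zero grand-total need, zero at-most days, zero
requirement, and zero population all raise classed errors
(`pc_zero_need_error`, `pc_zero_burden_error`, `pc_zero_requirement_error`,
`pc_validation_error`) rather than returning `NaN`; the vectorised
`opioid_access()` table returns `NA` for the affected ratios instead, so a
single empty country cannot abort a regional run. Countries flagged as
having no data are excluded from every aggregate and printed as
`"No data"` — exclusion, never imputation.

# What the synthetic generator emulates — and what it does not

`make_scenario()` plants a region of 21 countries (3 low-, 7 lower-middle-,
5 upper-middle-, 6 high-income, optionally plus one no-data country):

- populations log-uniform within income-group ranges; serious-illness
  deaths = population × group mortality rate (0.45% low down to 0.20%
  high) × normalised condition weights × lognormal noise (σ = 0.15);
- condition mixes shift from infectious/neonatal/nutritional causes in
  low-income groups toward cancer, dementia, and vascular disease in
  high-income ones; optionally the first low-income country's deaths are
  re-weighted to 80% HIV/AIDS, reproducing the situation where a single
  epidemic generates over 70% of a country's palliative care need;
- non-decedent cases are generated directly as deaths × per-condition
  case:death ratios × noise — not derived from incidence and duration,
  because the framework defines non-decedents only as prevalent non-fatal
  cases, with no derivation rule;
- opioid supply is planted as a known income-group fraction of the modelled
  requirement (defaults 0.5%, 10%, 50%, 150%), decomposed across four
  non-methadone products with Dirichlet shares plus a methadone record the
  DOME accounting must ignore. This makes access metrics *closed-loop
  testable*: the pipeline must return exactly 100 × fraction percent.

All randomness comes from sub-seeds of one integer seed, drawn before
populations are applied, so a run is fully reproducible and expected counts
scale exactly with supplied populations.

What the generator does **not** emulate: age/sex structure, calibration to
real mortality or narcotics marginals, correlation between a country's
income and its coefficient quality, and reporting error. Passing tests
therefore demonstrate that the accounting is exact and its invariants hold
under the assumed structure — they do not validate the need fractions,
symptom coefficients, or staffing norms against real populations. Those
remain planning assumptions to be replaced, table by table, with
jurisdiction-specific values.

# Numerical and testing choices

Oracle-equivalence tests compare every pipeline quantity with independent
brute-force loop recomputations at 1e-9 relative tolerance on 100 random
small scenarios (2–5 countries, 2–6 conditions) — sizes chosen to keep the
whole suite's runtime around a minute while exercising every code path,
including empty symptom sets and zero caseloads. Property suites run the
full generator at 1 country per income group. Scenario persistence writes
doubles with 17 significant digits, which is sufficient for bit-exact
write/read round-trips; report CSVs are written deterministically so
identical scenario + seed reruns are byte-identical, and the run manifest
records a content hash of the scenario and configuration.

# Known limitations

- Social and spiritual suffering are not quantified; only the human
  resources that would address them (social workers, spiritual counsellors)
  are carried in the staffing norms.
- Symptom-day bounds ignore severity gradation within "moderate or severe"
  and day-level co-occurrence.
- DOME is a national aggregate: it says nothing about within-country
  distribution, formulation mix, or diversion.
- The workforce model is workload-based; it does not model supervision
  hierarchies, travel time, or attrition.
- Reported reference tables carry their source's internal inconsistencies
  (three density cells normalised from unrounded FTE counts, one duplicated
  home-visit total); these are documented in
  `inst/extdata/reported/README.txt` and excluded from arithmetic checks
  rather than reconciled.
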