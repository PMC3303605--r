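---
title: "Methods: static ageing, statistical matching and income imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static ageing, statistical matching and income imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfusion)
```

popfusion models an urban population for medical-insurance policy analysis by
*static ageing*: instead of simulating births, deaths and migration for each
person, a cross-sectional census sample is carried to later years by
recalibrating its sampling weights to external benchmark totals, and
administrative attributes (insurance status, income) are fused onto it by
statistical matching. This vignette explains each stage's model, its
assumptions, the tunable parameters and the numerical choices, and what the
synthetic data generator can and cannot tell you about behaviour on real
microdata.

## 1. The base sample and cloning

The pipeline assumes a household-structured person file: one row per person
with household id, sex, age, residential status (urban/rural), ethnic
nationality (Han/minority), education (six categories including "under 6"),
employment status, marital status, living resource for nonworking adults, and
a sampling weight. The reference scenario is a 0.095% census sample of 5,395
persons in 1,761 households representing a population of 5.78 million.

`clone_sample()` replicates the file `copies` times (household structures
intact, fresh ids) and sets every weight to
`target_population / (n × (copies + 1))`. Cloning a 0.095% sample 115 times
produces 625,820 records — a ~10% sample — so that downstream matching can
give otherwise identical people *different* insurance statuses: one person of
weight 116w becomes 116 persons of weight w. The weight in the reference
scenario is 5,781,300 / 625,820 = 9.23796. Cloning changes no distribution;
it only refines the grain at which attributes can vary.

## 2. Calibration reweighting (GREG)

Let `d` be the initial weights and `X` the person × target indicator matrix
over the five benchmark dimensions (sex 2, age groups 8, residence 2,
nationality 2, education 6) plus an explicit grand-total column.
`greg_calibrate()` minimises the chi-square distance
`Σ dᵢ(wᵢ/dᵢ − 1)²` subject to `Xᵀw = T`, whose solution is the linear
calibration estimator `w = d(1 + Xλ)`, `λ = (XᵀDX)⁻¹(T − Xᵀd)`. Numerical
choices:

* **Redundant targets.** Each dimension's columns sum to the total column, so
  the full system is rank deficient by one column per dimension. A pivoted QR
  of `XᵀX` selects a maximal independent column set; the dropped columns are
  reported, and residuals are still checked against *every* target.
* **Benchmark reconciliation.** Published totals are printed to the nearest
  ten, so a dimension can miss the grand total by a few tens; each dimension
  is proportionally rescaled onto the grand total before solving
  (`reconcile_benchmark()`, adjustment factors logged as an attribute).
  Without this step the constraints would be mutually inconsistent and no
  exact solution would exist.
* **Bounds.** Pure chi-square calibration can produce negative or explosive
  weights. Weights are truncated to `[0.1, 10] × d` (defaults) and the free
  units re-solved, up to 50 iterations — the classic truncated-linear
  (GREGWT-style) scheme. The lower bound is strictly positive because
  negative person weights have no population interpretation. If truncation
  exhausts the free units before the targets are met the result is returned
  with `converged = FALSE` and full per-target diagnostics; it never fails
  silently.
* **Convergence.** Relative error ≤ 1e-6 on every target (default). On
  synthetic data the unbounded interior solution is typically reached in one
  or two iterations with residuals at machine precision.
* **Household integration.** Ageing holds household structures fixed, so by
  default all members of a household share one weight: indicator rows are
  aggregated within household and the solve runs at household level, which
  still honours the person-level benchmarks (the aggregated constraint is the
  same sum). A person-level mode exists for testing and for files without
  household structure. Whether the original study calibrated persons or
  households is not documented; integrated is the default here because the
  household structures are explicitly carried unchanged.

## 3. Projection of totals and benchmark tables

`geometric_growth_rate()` and `project_total()` implement constant-rate
geometric growth. The 2000–2005 overall rate that reproduces the observed
2005 total from the 2000 census count is 1.0315%/yr; the published value
1.031% is its truncation to three decimals, and compounding 1.031% from
5,781,300 indeed lands on 6.0855 million. The 2010 rate applies a
proportional-decrement rule: the natural rate fell 0.114 points between 2000
and 2005, so the overall rate is assumed to fall by the same *proportion*,
`0.114 × 1.031/0.743 = 0.158` points, giving 0.873% (rounded). **The
unrounded rate is canonical**: compounding it five years from 6,085,700 gives
exactly the published 2010 total 6,355,960 after rounding to the nearest ten,
whereas compounding the rounded 0.873% does not.

`build_benchmarks()` turns the 2005 table into 2006–2010 tables from
`structure_assumptions()`:

* sex shares carried from 2005 (51.19 / 48.81);
* the 0–14 age-block share reduced by 1.27 percentage points; the detailed
  eight-group allocation scales each block's 2005 within-block shares
  proportionally (the original detailed allocation followed an unspecified
  "ageing population" principle, so the published 2010 single-group values
  differ somewhat; the shipped 2010 fixture is authoritative where they do);
* the published 2010 65+ share is 9.83% although carrying the 15–64 share
  unchanged implies 9.92% — the two published rules are mutually
  inconsistent. `structure_assumptions(share_65plus = 9.83)` defaults to the
  published value; passing `NULL` applies the strict carry-over rule instead;
* urban share 61.14%; Han and minority totals grown by +4.41% / +9.63% and
  rescaled to the projected total — this rescaling reproduces the published
  2010 nationality totals exactly;
* education shares over the 6-and-over population, with an assumed under-6
  share, both exposed as parameters;
* intermediate years 2006–2009: shares interpolate linearly between the 2005
  and 2010 anchors (the original interpolation is undocumented; linearity is
  this package's declared choice), and totals compound the unrounded 2010
  rate. All published-style totals are rounded to the nearest ten.

## 4. Statistical matching

The insured administrative file is assembled by
`assemble_insured_population()`: municipal records are observed; provincial
participants and senior retirees have no individual records and are imputed
as random clones of municipal records, senior clones only from donors older
than 68 (the reported age floor of that cohort). The matching sample size per
group is `population / average census weight` (`stratum_sample_size()`).

Matching runs inside cell groups — sex × six age groups (15–24 … 65+) ×
employee/retiree × marital status, 72 cells, some legitimately empty (young
retirees). Where the insured demand exceeds census supply in a cell,
`resolve_deficits()` moves the surplus to the *closest* cell with slack,
closeness ordered by employment status match, then smallest age-group
distance, then marital status, then sex (the original adjustment is
undocumented; this ordering is the package's choice, and every move is
logged). Within each cell both sides are sorted by age, ties broken by record
id for determinism, and paired by rank: for a single matching variable this
provably minimises the total absolute difference (and the tests verify it
against exhaustive enumeration). The general weighted, variance-scaled
multi-variable distance is implemented as an extension with a greedy
nearest-neighbour pairing; the single-variable configuration is canonical.

After matching, `adjust_weights()` rescales a group's weights by
`target / current weighted total` — used for the senior-retiree cohort, whose
weighted total must be pulled down each year as the cohort shrinks (e.g. a
coefficient of 3935/5750 ≈ 0.684).

## 5. Income imputation and family income

`classify_earner_groups()` partitions persons: employees/retirees in a family
with at least one basic-living-allowance recipient are `low`; other
employees/retirees are `general`; nonworking adults living on the allowance,
property income or other sources are `other` and receive a fixed 210
Yuan/month (a parameter); everyone else — family-supported dependants,
pension-supported nonworkers, the unemployed, children — is `none` with zero
income. Pension-supported nonworkers are a deliberate edge case: the source
rules enumerate only allowance/property/other recipients for the fixed
assignment and set family-supported persons to zero, so pension income enters
this model only through matched retirees; treating those nonworkers as zero
understates their income and is flagged as a limitation.

`split_insured_donors()` splits the insured file per sex × age group ×
employment cell with `round(ratio × cell size)` low-income donors, ratios
defaulting to the census-observed low shares. `impute_donor_incomes()` then
draws a donor income within the recipient's stratum, with replacement only
when donors are scarce (logged), and falls back along nearest age group, then
sex, then employment status when a stratum is empty (each fallback logged);
it errors only when no donor exists at all. Donor pools are never modified.

`family_income_quintiles()` ranks families by annual income (12 × the
household's monthly sum), splits them into five groups each holding 20% of
total *family weight* — families kept whole, lower boundary inclusive — and
reports weighted mean incomes and the top/bottom ratio. Whether the original
quintiles weighted families or persons is not stated; family weight is this
package's choice, and because families are not split, realised quintile
weights deviate from 20% by at most one family's weight.

## 6. The synthetic generator: what it does and does not emulate

`synthetic_config()` defaults restate the study conditions: 1,761 households
with mean size ≈ 3.06 (≈ 5,395 persons), marginal targets equal to the
published 2000 distribution, living-resource shares for nonworking adults of
54.36% family support / 33.37% pension / 3.66% allowance / 3.23% property /
5.38% other, an insured-file stratum mix of 73.38/26.21/0.41 per cent
(municipal/provincial/senior), and roughly half of employees/retirees
insured. Values the study never states are set once to field-plausible
defaults and documented in `?synthetic_config`: employment and marital shares
by age group, a log-normal monthly income (median ≈ exp(6.9) ≈ 990 Yuan,
sdlog 0.5) with retiree and age-group shifts on the log scale, and a
household-size distribution over 1–8.

The generator reproduces *marginals*, not joint structure: ages, sex and
education are drawn independently (education independent of age above the
under-6 rule), residence and nationality are household-level draws, and
household composition uses plausibility rules only (adult head, rank-matched
partner ages so most partners are within a few years, random fill). Passing
tests therefore demonstrate that the *pipeline machinery* — calibration,
matching, imputation, reporting — is correct under controlled marginals; they
do not validate behaviour under the realistic joint dependence (age–education
correlation, assortative household composition, income–household clustering)
of true census microdata. All draws flow from a single seed in a documented
stream order, so every fixture is bit-reproducible; the insured file uses
`seed + 1` so the two files are independent but jointly reproducible.

## 7. Degenerate inputs and error behaviour

Empty person files error in `clone_sample()` and `family_income_quintiles()`;
an insured request with no eligible employees/retirees returns an empty file
with a warning; unmapped benchmark categories name the offending record and
field; per-cell count mismatches in matching name the cell; a singular
calibration system (conflicting benchmarks with nothing at a bound) errors
with a pruning hint, while bound-exhaustion returns a diagnosable
non-converged result; infeasible deficit resolution (more insured than census
records overall) errors outright.

## 8. Problem sizes

The shipped tests run the calibration property suite on a cloned synthetic
file of about 10⁵ persons (residuals ≤ 1e-6 on every benchmark), verify the
GREG optimum against a pseudo-inverse quadratic-programming oracle on
instances of ≤ 10 units, verify rank matching against exhaustive enumeration
on cells of ≤ 8 records, and exercise the full pipeline at a few hundred
households with 1–3 clone copies — sizes chosen so the whole suite stays
interactive (well under a minute) while every property is tested at a scale
where failures would be visible. The end-to-end example in the README uses
the reference sample scale (1,761 households, 10-fold cloning).

## 9. Known limitations

* No variance estimation or replicate weights — point weights only.
* No cohort-component projection (aggregate geometric rates only).
* The multi-variable matching distance uses a greedy pairing, not an optimal
  assignment solver; only the single-variable rank pairing is provably
  optimal.
* Synthetic data validate machinery, not realism (see §6).
* Published per-person disposable-income figures depend on the confidential
  administrative incomes and cannot be reproduced from synthetic data; the
  package reports whatever its inputs imply and asserts nothing about those
  published values.
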