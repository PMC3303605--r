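# popfusion

Static-ageing microsimulation of an urban population for medical-insurance
coverage analysis. The package implements the full pipeline used to model the
urban population of a Chinese pilot city for the urban-residents medical
insurance reform: a small household-structured census sample is cloned and
reweighted to later-year demographic benchmarks, an administrative file of
insured employees and retirees is statistically matched onto the census file,
and monthly incomes are imputed from insured donors — yielding person-level
population-group tables (insured/uninsured employees and retirees, residents
out of the labour force) and family-income quintile summaries. Because the
original microdata are confidential, the package ships a synthetic generator
that reproduces their statistical structure, so every stage is runnable and
testable end to end.

It is written for quantitative social scientists and health-policy modellers
working in R: every user-facing function takes a data frame and returns a
tibble, fitted objects have `tidy()`/`glance()` methods, and each result type
has an `autoplot()` or `plot_*()` companion.

## The methods in brief

**Calibration reweighting (GREG).** Given initial weights `d` and a 0/1
indicator matrix `X` (one column per benchmark category over sex, eight age
groups, residential status, nationality and education), calibration finds the
weights

```
w = argmin Σᵢ dᵢ (wᵢ/dᵢ − 1)²   subject to   Xᵀw = T,
```

whose closed form is `w = d(1 + Xλ)` with `λ` solving
`(XᵀDX)λ = T − Xᵀd`. Weights are kept inside `[0.1, 10] × d` by truncate-and-
resolve iterations (the GREGWT family), and household-integrated mode gives
all members of a household one shared weight while still honouring
person-level benchmarks.

**Projection arithmetic.** Annual geometric growth rates
`((p₁/p₀)^(1/y) − 1) × 100`, a proportional-decrement rule for the 2010 rate
(`1.031% − 0.114% × 1.031/0.743 = 0.873%`), and share rules that turn the 2005
benchmark table into tables for 2006–2010.

**Statistical matching.** Insured records are paired with census records
inside 72 cell groups (sex × six age groups × employee/retiree × marital
status). Within a cell the match minimises the distance

```
d_{i,k} = Σⱼ a_j (x_MIP,i,j,k − x_CP,i,j,k)² / σ²_j ,
```

which for the default single matching variable (age) reduces to the absolute
age difference; sorting both sides by age and pairing by rank is then exactly
optimal. Matched census persons inherit insurance status, administrative
stratum and monthly income.

**Income imputation.** Employees/retirees in families receiving the basic
living allowance are low-income earners, the rest are general earners; each
draws a donor income within sex × age group × employment strata from the
correspondingly split insured file. Allowance/property/other-income
nonworkers receive a fixed 210 Yuan/month; dependants get zero. Family annual
income (12 × the household's monthly sum) is summarised in weighted quintiles.

## Worked example

```r
library(popfusion)

cfg <- run_config(
  seed      = 1,
  synthetic = synthetic_config(n_households = 1761),  # ~5,395 persons
  copies    = 9,                                      # cloned to ~54,000
  years     = 2005
)
rep <- run_pipeline(cfg)
rep
#> <run_report>
#> population groups:
#>  year     population_group population     share
#>  2005     insured employee  1448958.8 23.809237
#>  2005      insured retiree   331512.3  5.447398
#>  2005             resident  2218320.4 36.451360
#>  2005   uninsured employee  1576967.7 25.912675
#>  2005    uninsured retiree   352341.8  5.789667
#>  2005 uninsured unemployed   157599.1  2.589662
#> match quality:
#>  n_pairs mean_age_gap max_age_gap share_gap_lt4
#>    15130    0.3610707          18      0.994382
#> mean disposable income (Yuan/yr): 8543.12
```

The group table partitions the calibrated 2005 population of 6,085,700: about
29% of people are insured employees or retirees, another 32% are employed or
retired without insurance, and 36% are residents out of the labour force —
the target group of the urban-residents insurance scheme. The match-quality
block shows the 15,130 insured sample records were paired with census records
at a mean age gap of 0.36 years, 99.4% of pairs within 4 years. Quintile
summaries and plots:

```r
glance(rep$income_quintiles)
#> # A tibble: 1 × 3
#>   n_families middle_quintile_income top_bottom_ratio
#>        <int>                  <dbl>            <dbl>
#> 1      17610                 23063.             12.4
autoplot(rep$income_quintiles)   # quintile bar chart
plot_age_trends(rep)             # age-structure trends across years
```

Lower-level pieces are ordinary functions on tibbles, e.g.

```r
s   <- generate_census_sample(synthetic_config(n_households = 1761, seed = 1))
cl  <- clone_sample(s$persons, copies = 115, target_population = 5781300)
fit <- calibrate_to_benchmark(cl, benchmark_fixture(2005))
glance(fit$result)   # converged, max |rel. error| ~ 1e-15
```

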