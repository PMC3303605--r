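#' Configuration for the synthetic microdata generator
#'
#' Bundles every tunable of the synthetic census-sample and insured-file
#' generators, validated at construction. Defaults emulate the study
#' conditions of the source data: 1,761 households averaging about 3.06
#' persons (so roughly 5,395 persons), the 2000 published marginal
#' distributions, living-resource shares for nonworking adults of 54.36%
#' family support / 33.37% pension / 3.66% basic living allowance / 3.23%
#' property income / 5.38% other, and an insured-file stratum mix of 73.38%
#' municipal / 26.21% provincial / 0.41% senior retirees.
#'
#' @param n_households Number of households to generate.
#' @param household_size_probs Probability vector over household sizes 1..8.
#'   The default has mean ~3.06 persons per household.
#' @param marginal_targets Benchmark table whose shares the generated sample
#'   should reproduce (default: the published 2000 table).
#' @param employment_shares Named list, one entry per matching age group
#'   (`15-24` ... `65+`), each a named probability vector over
#'   `employee`, `retiree`, `unemployed`, `nonworking`. Persons under 15 are
#'   always `child`.
#' @param marital_shares Named list like `employment_shares`, probabilities
#'   over `never married`, `married`, `divorced/other`. Persons under 15 are
#'   always `never married`.
#' @param living_resource_shares Probabilities over the five living-resource
#'   categories, applied to nonworking persons aged 15+.
#' @param insured_fraction Fraction of employees/retirees who appear in the
#'   insured administrative file, in `[0, 1]`.
#' @param stratum_probs Probabilities of the municipal/provincial/senior
#'   administrative strata for insured records. Senior records require age
#'   above 68, so the realised senior share can fall short when few such
#'   donors exist.
#' @param income_model List with `meanlog`, `sdlog` (log-normal monthly income
#'   in Yuan), `retiree_shift` (added to `meanlog` for retirees) and
#'   `age_shifts` (named numeric, one per matching age group, added to
#'   `meanlog`).
#' @param low_income_threshold Monthly income (Yuan) below which an insured
#'   record is flagged low-income.
#' @param partner_prob Probability that a household of size >= 2 contains a
#'   spouse/partner for the head.
#' @param disabled_rate Probability that a person aged 15+ is disabled (used
#'   for concession classification downstream).
#' @param student_rate_tertiary Probability that a nonworking 18-24 year old
#'   with tertiary education is a university student.
#' @param seed Integer RNG seed; all generator draws flow from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_households = 1761,
    household_size_probs = c(0.155, 0.225, 0.27, 0.195, 0.09, 0.04, 0.018, 0.007),
    marginal_targets = benchmark_fixture(2000),
    employment_shares = default_employment_shares(),
    marital_shares = default_marital_shares(),
    living_resource_shares = c(
      "family support" = 0.5436, "pension" = 0.3337,
      "basic living allowance" = 0.0366, "property income" = 0.0323,
      "other" = 0.0538
    ),
    insured_fraction = 0.48,
    stratum_probs = c(municipal = 0.7338, provincial = 0.2621, senior = 0.0041),
    income_model = default_income_model(),
    low_income_threshold = 450,
    partner_prob = 0.85,
    disabled_rate = 0.015,
    student_rate_tertiary = 0.85,
    seed = NULL) {
  stopifnot(length(n_households) == 1, n_households >= 0)
  if (length(household_size_probs) != 8) {
    abort("`household_size_probs` must cover household sizes 1..8.")
  }
  check_prob_vector(household_size_probs, "household_size_probs")
  if (sum(household_size_probs * (1:8)) <= 0) {
    abort("`household_size_probs` must have positive mean size.")
  }
  validate_benchmark(marginal_targets)
  for (g in pop_levels$age_group6) {
    check_prob_vector(employment_shares[[g]], paste0("employment_shares$`", g, "`"))
    check_prob_vector(marital_shares[[g]], paste0("marital_shares$`", g, "`"))
  }
  check_prob_vector(living_resource_shares, "living_resource_shares")
  check_prob_vector(unname(stratum_probs), "stratum_probs")
  if (insured_fraction < 0 || insured_fraction > 1) {
    abort("`insured_fraction` must be in [0, 1].")
  }
  stopifnot(is.list(income_model),
            all(c("meanlog", "sdlog", "retiree_shift", "age_shifts") %in%
                  names(income_model)))
  structure(
    list(
      n_households = as.integer(n_households),
      household_size_probs = household_size_probs,
      marginal_targets = marginal_targets,
      employment_shares = employment_shares,
      marital_shares = marital_shares,
      living_resource_shares = living_resource_shares,
      insured_fraction = insured_fraction,
      stratum_probs = stratum_probs,
      income_model = income_model,
      low_income_threshold = low_income_threshold,
      partner_prob = partner_prob,
      disabled_rate = disabled_rate,
      student_rate_tertiary = student_rate_tertiary,
      seed = seed
    ),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_employment_shares <- function() {
  list(
    `15-24` = c(employee = 0.42, retiree = 0.00, unemployed = 0.04, nonworking = 0.54),
    `25-34` = c(employee = 0.82, retiree = 0.00, unemployed = 0.04, nonworking = 0.14),
    `35-44` = c(employee = 0.85, retiree = 0.00, unemployed = 0.03, nonworking = 0.12),
    `45-54` = c(employee = 0.78, retiree = 0.08, unemployed = 0.03, nonworking = 0.11),
    `55-64` = c(employee = 0.33, retiree = 0.55, unemployed = 0.01, nonworking = 0.11),
    `65+`   = c(employee = 0.02, retiree = 0.73, unemployed = 0.00, nonworking = 0.25)
  )
}

#' @rdname synthetic_config
#' @export
default_marital_shares <- function() {
  list(
    `15-24` = c("never married" = 0.85, married = 0.14, "divorced/other" = 0.01),
    `25-34` = c("never married" = 0.25, married = 0.70, "divorced/other" = 0.05),
    `35-44` = c("never married" = 0.08, married = 0.85, "divorced/other" = 0.07),
    `45-54` = c("never married" = 0.04, married = 0.88, "divorced/other" = 0.08),
    `55-64` = c("never married" = 0.03, married = 0.87, "divorced/other" = 0.10),
    `65+`   = c("never married" = 0.02, married = 0.80, "divorced/other" = 0.18)
  )
}

#' @rdname synthetic_config
#' @export
default_income_model <- function() {
  list(
    meanlog = 6.9,   # exp(6.9) ~ 992 Yuan/month at the median
    sdlog = 0.5,
    retiree_shift = -0.25,
    age_shifts = c(`15-24` = -0.35, `25-34` = 0, `35-44` = 0.15,
                   `45-54` = 0.20, `55-64` = 0.10, `65+` = 0)
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  households:      ", x$n_households, "\n")
  cat("  mean hh size:    ", round(sum(x$household_size_probs * 1:8), 3), "\n")
  cat("  target year:     ", unique(x$marginal_targets$year), "\n")
  cat("  insured fraction:", x$insured_fraction, "\n")
  cat("  seed:            ", x$seed %||% "<unset>", "\n")
  invisible(x)
}
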