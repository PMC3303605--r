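# Synthetic household microdata: a stand-in for the confidential census
# sample and insured administrative file, matching their marginal structure.
# Only marginals are benchmarked downstream, so household composition uses
# simple plausibility rules (adult head, rank-matched partner ages, random
# fill), not an estimated joint distribution.

# internal: sample/permute the elements of x itself (never 1:x)
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

# internal: per-dimension target shares (fractions) from a benchmark table
target_shares <- function(benchmark, dimension) {
  rows <- benchmark[benchmark$dimension == dimension, ]
  setNames(rows$total / sum(rows$total), rows$category)
}

# internal: uniform integer age within an 8-level age group (65+ spans 65-90)
draw_age_in_group <- function(group) {
  lo <- c(`0-4` = 0, `5-14` = 5, `15-24` = 15, `25-34` = 25, `35-44` = 35,
          `45-54` = 45, `55-64` = 55, `65+` = 65)[group]
  hi <- c(`0-4` = 4, `5-14` = 14, `15-24` = 24, `25-34` = 34, `35-44` = 44,
          `45-54` = 54, `55-64` = 64, `65+` = 90)[group]
  lo + floor(runif(length(group)) * (hi - lo + 1))
}

# internal: vectorised conditional categorical draw: one probability vector
# per matching age group
draw_by_age_group <- function(group6, shares_by_group) {
  out <- rep(NA_character_, length(group6))
  for (g in unique(group6[!is.na(group6)])) {
    idx <- which(group6 == g)
    p <- shares_by_group[[g]]
    out[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  out
}

#' Generate a household-structured synthetic census sample
#'
#' Draws household sizes, fills households with persons whose attribute
#' marginals converge to the configured benchmark shares as the sample grows,
#' and applies simple composition rules: every household has a head aged 18+,
#' households of two or more usually contain a partner with a similar age, and
#' remaining members are allocated at random (so children are mostly much
#' younger than the head). Residential status and nationality are drawn at the
#' household level; all other attributes per person. Education is drawn from
#' the 6-and-over marginal independent of age (beyond the under-6 rule), which
#' keeps every marginal on target at the cost of some person-level
#' plausibility.
#'
#' All draws flow from `config$seed` in a fixed stream order (household sizes,
#' age groups, ages, head/partner/fill assignment, household residence and
#' nationality, then per-person sex, education, employment, marital status,
#' living resource, student and disabled flags), so regeneration is
#' bit-identical.
#'
#' @param config A [synthetic_config()].
#' @return A list with tibbles `households` (`household_id`, `size`,
#'   `residential_status`, `nationality`) and `persons` (one row per person
#'   with demographic attributes, household link, and unit `weight`).
#' @export
#' @examples
#' cfg <- synthetic_config(n_households = 50, seed = 1)
#' sample <- generate_census_sample(cfg)
#' dplyr::count(sample$persons, sex)
generate_census_sample <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run <- function() generate_census_sample_impl(config)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

generate_census_sample_impl <- function(config) {
  n_hh <- config$n_households
  empty_persons <- tibble(
    person_id = character(), household_id = character(),
    sex = character(), age = integer(), residential_status = character(),
    nationality = character(), education = character(),
    employment_status = character(), marital_status = character(),
    living_resource = character(), student = logical(), disabled = logical(),
    weight = numeric()
  )
  empty_households <- tibble(
    household_id = character(), size = integer(),
    residential_status = character(), nationality = character()
  )
  if (n_hh == 0) return(list(households = empty_households, persons = empty_persons))

  bm <- config$marginal_targets
  sizes <- sample(1:8, n_hh, replace = TRUE, prob = config$household_size_probs)
  n <- sum(sizes)
  hh_ids <- sprintf("H%06d", seq_len(n_hh))

  # ages
  age_shares <- target_shares(bm, "age_group")
  grp <- sample(names(age_shares), n, replace = TRUE, prob = age_shares)
  age <- as.integer(draw_age_in_group(grp))

  # every household needs an adult head; promote the oldest minors if short
  adult <- age >= 18
  if (sum(adult) < n_hh) {
    shortfall <- n_hh - sum(adult)
    promote <- order(age, decreasing = TRUE)[!adult[order(age, decreasing = TRUE)]][seq_len(shortfall)]
    age[promote] <- 18L
    adult <- age >= 18
  }

  # heads: one random adult per household
  adult_idx <- sample_vec(which(adult))
  head_idx <- adult_idx[seq_len(n_hh)]
  remaining_adults <- adult_idx[-seq_len(n_hh)]

  # partners: rank-matched ages so |age difference| stays small
  hh_of <- integer(n)
  hh_of[head_idx] <- seq_len(n_hh)
  open <- sizes - 1L
  eligible_hh <- which(open > 0 & runif(n_hh) < config$partner_prob)
  k <- min(length(eligible_hh), length(remaining_adults))
  if (k > 0) {
    chosen_hh <- if (length(eligible_hh) > k) sample_vec(eligible_hh, k) else eligible_hh
    partner_pool <- if (length(remaining_adults) > k) sample_vec(remaining_adults, k) else remaining_adults
    chosen_hh <- chosen_hh[order(age[head_idx[chosen_hh]])]
    partner_pool <- partner_pool[order(age[partner_pool])]
    hh_of[partner_pool] <- chosen_hh
    open[chosen_hh] <- open[chosen_hh] - 1L
    remaining_adults <- setdiff(remaining_adults, partner_pool)
  }

  # fill the rest at random
  unassigned <- sample_vec(which(hh_of == 0))
  slots <- rep(seq_len(n_hh), open)
  hh_of[unassigned] <- slots

  # household-level dimensions
  res_shares <- target_shares(bm, "residential_status")
  nat_shares <- target_shares(bm, "nationality")
  hh_res <- sample(names(res_shares), n_hh, replace = TRUE, prob = res_shares)
  hh_nat <- sample(names(nat_shares), n_hh, replace = TRUE, prob = nat_shares)

  # person-level attributes
  sex_shares <- target_shares(bm, "sex")
  sex <- sample(names(sex_shares), n, replace = TRUE, prob = sex_shares)

  edu_shares <- target_shares(bm, "education")
  edu6 <- edu_shares[setdiff(names(edu_shares), "under 6")]
  edu6 <- edu6 / sum(edu6)
  education <- rep("under 6", n)
  over5 <- which(age >= 6)
  education[over5] <- sample(names(edu6), length(over5), replace = TRUE, prob = edu6)

  g6 <- age_group6(age)
  employment <- draw_by_age_group(g6, config$employment_shares)
  employment[age < 15] <- "child"

  marital <- draw_by_age_group(g6, config$marital_shares)
  marital[age < 15] <- "never married"

  living <- rep(NA_character_, n)
  nw <- which(employment == "nonworking" & age >= 15)
  if (length(nw) > 0) {
    living[nw] <- sample(names(config$living_resource_shares), length(nw),
                         replace = TRUE,
                         prob = config$living_resource_shares)
  }

  student <- age >= 6 & age <= 17
  uni <- which(employment == "nonworking" & age >= 18 & age <= 24 &
                 education == "tertiary")
  if (length(uni) > 0) {
    student[uni] <- runif(length(uni)) < config$student_rate_tertiary
  }

  disabled <- rep(FALSE, n)
  ad <- which(age >= 15)
  disabled[ad] <- runif(length(ad)) < config$disabled_rate

  persons <- tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    household_id = hh_ids[hh_of],
    sex = sex,
    age = age,
    residential_status = hh_res[hh_of],
    nationality = hh_nat[hh_of],
    education = education,
    employment_status = employment,
    marital_status = marital,
    living_resource = living,
    student = student,
    disabled = disabled,
    weight = 1
  ) |> arrange(.data$household_id, .data$person_id)

  households <- tibble(
    household_id = hh_ids, size = as.integer(sizes),
    residential_status = hh_res, nationality = hh_nat
  )
  list(households = households, persons = persons)
}

#' Generate a synthetic insured administrative file
#'
#' Draws a fraction of the census file's employees and retirees into an
#' administrative medical-insurance file, assigns municipal/provincial/senior
#' strata (senior records only among persons aged above 68), and attaches
#' log-normal monthly incomes with age-group and retiree shifts. Uses
#' `config$seed + 1L` so census and insured draws come from distinct,
#' reproducible streams.
#'
#' @param config A [synthetic_config()].
#' @param persons Census persons tibble from [generate_census_sample()].
#' @return Tibble of insured records: `record_id`, `person_id` (the census
#'   source record), `stratum`, `sex`, `age`, `employment_status`,
#'   `marital_status`, `monthly_income`, `low_income_flag`.
#' @export
generate_insured_file <- function(config, persons) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(persons) == 0) abort("`persons` must be nonempty.")
  run <- function() generate_insured_file_impl(config, persons)
  if (!is.null(config$seed)) withr::with_seed(config$seed + 1L, run()) else run()
}

generate_insured_file_impl <- function(config, persons) {
  empty <- tibble(
    record_id = character(), person_id = character(), stratum = character(),
    sex = character(), age = integer(), employment_status = character(),
    marital_status = character(), monthly_income = numeric(),
    low_income_flag = logical()
  )
  eligible <- filter(persons, .data$employment_status %in% c("employee", "retiree"))
  if (nrow(eligible) == 0) {
    warn("No employees or retirees in `persons`; returning an empty insured file.")
    return(empty)
  }
  n_ins <- round(config$insured_fraction * nrow(eligible))
  if (n_ins == 0) return(empty)
  picked <- slice_sample(eligible, n = n_ins)

  # senior stratum requires age > 68; shortfalls fall back to municipal
  p <- config$stratum_probs
  n_senior <- rbinom(1, n_ins, p[["senior"]])
  senior_ok <- which(picked$age > 68)
  n_senior <- min(n_senior, length(senior_ok))
  stratum <- rep(NA_character_, n_ins)
  if (n_senior > 0) {
    stratum[sample_vec(senior_ok, n_senior)] <- "senior"
  }
  rest <- which(is.na(stratum))
  pm <- p[c("municipal", "provincial")] / sum(p[c("municipal", "provincial")])
  stratum[rest] <- sample(c("municipal", "provincial"), length(rest),
                          replace = TRUE, prob = pm)

  im <- config$income_model
  meanlog <- im$meanlog +
    im$age_shifts[age_group6(picked$age)] +
    im$retiree_shift * (picked$employment_status == "retiree")
  income <- round(rlnorm(n_ins, meanlog = meanlog, sdlog = im$sdlog), 2)

  tibble(
    record_id = sprintf("I%07d", seq_len(n_ins)),
    person_id = picked$person_id,
    stratum = stratum,
    sex = picked$sex,
    age = picked$age,
    employment_status = picked$employment_status,
    marital_status = picked$marital_status,
    monthly_income = income,
    low_income_flag = income < config$low_income_threshold
  )
}
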