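#' Canonical category levels used throughout the package
#'
#' All person-level categorical variables are plain character vectors drawn
#' from these level sets; benchmark tables and cell keys use the same spelling,
#' so joins and indicator matrices never need recoding.
#'
#' @format A named list of character vectors: `sex`, `age_group` (the eight
#'   benchmark age groups), `age_group6` (the six matching age groups, 15+),
#'   `residential_status`, `nationality`, `education`, `employment_status`,
#'   `marital_status`, `living_resource`, `stratum`, `earner_group`.
#' @export
pop_levels <- list(
  sex                = c("male", "female"),
  age_group          = c("0-4", "5-14", "15-24", "25-34", "35-44", "45-54",
                         "55-64", "65+"),
  age_group6         = c("15-24", "25-34", "35-44", "45-54", "55-64", "65+"),
  residential_status = c("urban", "rural"),
  nationality        = c("Han", "minority"),
  education          = c("tertiary", "senior secondary", "junior secondary",
                         "primary", "other", "under 6"),
  employment_status  = c("employee", "retiree", "unemployed", "nonworking",
                         "child"),
  marital_status     = c("never married", "married", "divorced/other"),
  living_resource    = c("family support", "pension",
                         "basic living allowance", "property income", "other"),
  stratum            = c("municipal", "provincial", "senior"),
  earner_group       = c("low", "general", "other", "none")
)

#' Assign ages to the eight benchmark age groups
#'
#' Breaks follow the population-survey convention: 0-4, 5-14, then decades to
#' 64, with 65 and over open-ended.
#'
#' @param age Integer vector of ages in years (>= 0).
#' @return Character vector of age-group labels.
#' @export
#' @examples
#' age_group8(c(0, 5, 17, 64, 65, 90))
age_group8 <- function(age) {
  stopifnot(is.numeric(age), all(age >= 0, na.rm = TRUE))
  cut(age, breaks = c(0, 5, 15, 25, 35, 45, 55, 65, Inf), right = FALSE,
      labels = pop_levels$age_group) |> as.character()
}

#' Assign ages to the six matching age groups (15 years and over)
#'
#' These are the age groups of the statistical-matching cell key; ages below
#' 15 return `NA` because persons under the working age are never matched.
#'
#' @inheritParams age_group8
#' @return Character vector of labels, `NA` below age 15.
#' @export
age_group6 <- function(age) {
  stopifnot(is.numeric(age), all(age >= 0, na.rm = TRUE))
  out <- cut(age, breaks = c(15, 25, 35, 45, 55, 65, Inf), right = FALSE,
             labels = pop_levels$age_group6) |> as.character()
  out
}

# internal: validate a probability vector
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) abort(paste0("`", what, "` has negative entries."))
  if (abs(sum(p) - 1) > tol) {
    abort(paste0("`", what, "` must sum to 1 (got ", format(sum(p)), ")."))
  }
  invisible(p)
}

# internal: round to the nearest ten, the printing convention of published
# benchmark totals
round_ten <- function(x) round(x / 10) * 10
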