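# Total-population projection and benchmark construction: geometric growth
# arithmetic on published totals, plus the share rules that turn the 2005
# benchmark table into tables for 2006-2010.

#' Average annual geometric growth rate between two populations
#'
#' @param p0,p1 Start and end populations (persons, > 0).
#' @param years Number of years elapsed (>= 1).
#' @return Rate in per cent per year: `((p1/p0)^(1/years) - 1) * 100`.
#' @export
#' @examples
#' geometric_growth_rate(5781300, 6085700, 5) # ~1.031
geometric_growth_rate <- function(p0, p1, years) {
  if (any(c(p0, p1) <= 0)) abort("Populations must be positive.")
  stopifnot(years >= 1)
  ((p1 / p0)^(1 / years) - 1) * 100
}

#' Project a population total forward at a constant growth rate
#'
#' @param p0 Base population.
#' @param rate Annual growth rate in per cent.
#' @param years Years to compound.
#' @param nearest_ten Round the result to the nearest ten, the printing
#'   convention of published totals.
#' @return Projected population (persons).
#' @export
#' @examples
#' project_total(5781300, 1.031, 5) / 1e6 # ~6.0855 million
project_total <- function(p0, rate, years, nearest_ten = FALSE) {
  stopifnot(is.finite(rate), p0 > 0, years >= 0)
  out <- p0 * (1 + rate / 100)^years
  if (nearest_ten) round_ten(out) else out
}

#' Growth-rate model linking the 2000 census, 2005 survey and 2010 projection
#'
#' The natural rate (births minus deaths) understates growth because it
#' ignores net in-migration; the overall rate is the geometric rate that
#' reproduces the observed 2005 total from the 2000 census. The survey
#' reported the natural rate falling by `decrement` percentage points between
#' 2000 and 2005; the 2010 overall rate is assumed to fall by the same
#' *proportion* of the overall rate, i.e. by
#' `decrement * adjusted_rate_2005 / natural_rate_2005`.
#'
#' @param natural_rate_2000,natural_rate_2005 Natural growth rates, %/yr.
#' @param adjusted_rate_2005 Overall (migration-adjusted) rate, %/yr.
#' @param decrement Reported fall in the natural rate 2000 to 2005,
#'   percentage points.
#' @param base_population_2005 2005 total used as the projection base.
#' @return A list of class `growth_model`.
#' @export
growth_model <- function(natural_rate_2000 = 0.857,
                         natural_rate_2005 = 0.743,
                         adjusted_rate_2005 = 1.031,
                         decrement = 0.114,
                         base_population_2005 = 6085700) {
  rates <- c(natural_rate_2000, natural_rate_2005, adjusted_rate_2005)
  if (any(rates <= -5 | rates >= 5)) abort("Rates must lie in (-5, 5) %/yr.")
  if (decrement < 0) abort("`decrement` must be >= 0.")
  structure(
    list(natural_rate_2000 = natural_rate_2000,
         natural_rate_2005 = natural_rate_2005,
         adjusted_rate_2005 = adjusted_rate_2005,
         decrement = decrement,
         base_population_2005 = base_population_2005),
    class = "growth_model"
  )
}

#' Overall growth rate assumed for 2006-2010
#'
#' Applies the proportional-decrement rule of [growth_model()]. The unrounded
#' rate is the canonical one: compounding it for five years from the 2005 base
#' reproduces the published 2010 total to the nearest ten, which the rounded
#' 0.873% does not.
#'
#' @param model A [growth_model()].
#' @return List with `rate` (unrounded %/yr), `rate_rounded` (3 decimals) and
#'   `decrement_2010` (the proportional decrement, %/yr).
#' @export
#' @examples
#' rate_2010(growth_model())$rate_rounded # 0.873
rate_2010 <- function(model) {
  stopifnot(inherits(model, "growth_model"))
  if (model$natural_rate_2005 == 0) abort("Natural 2005 rate must be nonzero.")
  dec <- model$decrement * model$adjusted_rate_2005 / model$natural_rate_2005
  rate <- model$adjusted_rate_2005 - dec
  list(rate = rate, rate_rounded = round(rate, 3), decrement_2010 = dec)
}

#' Structure assumptions for the 2010 benchmark table
#'
#' Defaults restate the published 2010 assumptions: sex shares carried from
#' 2005 (51.19/48.81), the 0-14 share down 1.27 percentage points, the 15-64
#' share carried, urban share up to 61.14%, Han and minority populations grown
#' 4.41% and 9.63% then rescaled to the projected total. The published 2010
#' table prints a 65+ share of 9.83% although the carry-over rule implies
#' 9.92%; the published value wins by default (`share_65plus = 9.83`), set it
#' `NULL` to apply the strict rule.
#'
#' @param sex_shares Named per-cent shares for male/female in 2010.
#' @param age_0_14_decrement Percentage-point fall of the 0-14 share vs 2005.
#' @param share_65plus Published 65+ share (%), or `NULL` to derive it as the
#'   remainder after the 0-14 and 15-64 rules.
#' @param nationality_growth Named growth factors applied to the 2005 Han and
#'   minority totals before rescaling.
#' @param urban_share 2010 urban share (%).
#' @param education_shares_6plus Named per-cent shares of the population aged
#'   6+ across the five education categories.
#' @param under6_share Share (%) of the total population aged under 6.
#' @return A list of class `structure_assumptions`.
#' @export
structure_assumptions <- function(
    sex_shares = c(male = 51.19, female = 48.81),
    age_0_14_decrement = 1.27,
    share_65plus = 9.83,
    nationality_growth = c(Han = 1.0441, minority = 1.0963),
    urban_share = 61.14,
    education_shares_6plus = c(
      tertiary = 8.55, `senior secondary` = 19.86,
      `junior secondary` = 30.97, primary = 32.50, other = 8.12
    ),
    under6_share = 6.65) {
  stopifnot(all(sex_shares >= 0 & sex_shares <= 100),
            age_0_14_decrement >= 0,
            urban_share >= 0 && urban_share <= 100)
  structure(
    list(sex_shares = sex_shares,
         age_0_14_decrement = age_0_14_decrement,
         share_65plus = share_65plus,
         nationality_growth = nationality_growth,
         urban_share = urban_share,
         education_shares_6plus = education_shares_6plus,
         under6_share = under6_share),
    class = "structure_assumptions"
  )
}

# internal: 2010 shares (fractions of the grand total) per dimension
shares_2010 <- function(base_2005, assumptions) {
  s05 <- benchmark_shares(base_2005)
  share05 <- function(dim, cat) {
    s05$share[s05$dimension == dim & s05$category == cat]
  }
  a <- assumptions

  sex <- a$sex_shares / sum(a$sex_shares) * 100

  # age blocks: 0-14 reduced, 15-64 carried, 65+ the published share (or the
  # remainder), then 8-group detail by proportional within-block scaling
  blk05 <- c(
    `0-14` = share05("age_group", "0-4") + share05("age_group", "5-14"),
    `15-64` = sum(purrr::map_dbl(c("15-24", "25-34", "35-44", "45-54", "55-64"),
                                 \(g) share05("age_group", g))),
    `65+` = share05("age_group", "65+")
  )
  blk10 <- c(`0-14` = blk05[["0-14"]] - a$age_0_14_decrement,
             `15-64` = blk05[["15-64"]],
             `65+` = NA_real_)
  blk10[["65+"]] <- a$share_65plus %||%
    (100 - blk10[["0-14"]] - blk10[["15-64"]])
  blk10[["15-64"]] <- 100 - blk10[["0-14"]] - blk10[["65+"]]
  within05 <- list(
    `0-14` = c("0-4", "5-14"),
    `15-64` = c("15-24", "25-34", "35-44", "45-54", "55-64"),
    `65+` = "65+"
  )
  age <- purrr::imap(within05, function(groups, blk) {
    w <- purrr::map_dbl(groups, \(g) share05("age_group", g))
    setNames(blk10[[blk]] * w / sum(w), groups)
  }) |> unlist() |> setNames(unlist(within05))

  urban <- c(urban = a$urban_share, rural = 100 - a$urban_share)

  nat_grown <- c(
    Han = base_2005$total[base_2005$dimension == "nationality" &
                            base_2005$category == "Han"] *
      a$nationality_growth[["Han"]],
    minority = base_2005$total[base_2005$dimension == "nationality" &
                                 base_2005$category == "minority"] *
      a$nationality_growth[["minority"]]
  )
  nat <- 100 * nat_grown / sum(nat_grown)

  edu6 <- a$education_shares_6plus / sum(a$education_shares_6plus) *
    (100 - a$under6_share)
  edu <- c(edu6, `under 6` = a$under6_share)

  list(sex = sex, age_group = age, residential_status = urban,
       nationality = nat, education = edu)
}

#' Build projected benchmark tables for target years
#'
#' Applies the 2010 structure rules to the 2005 base, converts shares to
#' category totals (rounded to the nearest ten, the published convention), and
#' linearly interpolates shares between the 2005 and 2010 anchors for
#' intermediate years. Totals for intermediate years compound the 2005 total
#' at the constant unrounded 2010 rate. Shares that fail to sum to 100 after
#' the rules are rescaled (the adjustment is part of the share arithmetic, not
#' an error).
#'
#' @param base_2005 The 2005 benchmark table.
#' @param assumptions A [structure_assumptions()].
#' @param total_2010 Projected 2010 total population.
#' @param years Years to build, a subset of 2006:2010.
#' @param rate Annual rate (%/yr) used for intermediate-year totals; defaults
#'   to the geometric rate implied by `base_2005` and `total_2010`.
#' @return A tibble of benchmark rows (`year`, `dimension`, `category`,
#'   `total`) covering all requested years.
#' @export
build_benchmarks <- function(base_2005, assumptions, total_2010,
                             years = 2006:2010, rate = NULL) {
  validate_benchmark(base_2005)
  stopifnot(inherits(assumptions, "structure_assumptions"),
            all(years %in% 2006:2010))
  total05 <- base_2005$total[base_2005$dimension == "total"]
  rate <- rate %||% geometric_growth_rate(total05, total_2010, 5)

  s05 <- benchmark_shares(base_2005)
  s10 <- shares_2010(base_2005, assumptions)
  s10_tbl <- purrr::imap(s10, \(v, d) tibble(dimension = d,
                                             category = names(v),
                                             share10 = unname(v))) |>
    bind_rows()
  anchors <- s05 |>
    select("dimension", "category", share05 = "share") |>
    left_join(s10_tbl, by = c("dimension", "category"))
  if (any(is.na(anchors$share10))) {
    abort("2010 share rules left categories without a share; check assumptions.")
  }

  purrr::map(years, function(y) {
    f <- (y - 2005) / 5
    tot <- if (y == 2010) total_2010 else {
      project_total(total05, rate, y - 2005, nearest_ten = TRUE)
    }
    shares <- anchors |>
      mutate(share = (1 - f) * .data$share05 + f * .data$share10) |>
      group_by(.data$dimension) |>
      mutate(share = .data$share / sum(.data$share) * 100) |>
      ungroup()
    bind_rows(
      tibble(year = y, dimension = "total", category = "total",
             total = round_ten(tot)),
      shares |>
        mutate(year = y, total = round_ten(.data$share / 100 * tot)) |>
        select("year", "dimension", "category", "total")
    )
  }) |> bind_rows()
}
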