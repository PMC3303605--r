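# Income imputation: classify census persons into earner groups, split the
# insured file into low/general donor pools, impute monthly incomes by
# stratified donor sampling, assign the fixed living allowance, and summarise
# family income by weighted quintiles.

#' Classify census persons into earner groups
#'
#' Rules: employees and retirees living in a family where at least one member
#' receives the basic living allowance are `low` income earners; all other
#' employees and retirees are `general`; nonworking persons aged 15+ whose
#' living resource is the allowance, property income or other sources are
#' `other` (they receive a fixed allowance income); everyone else — persons
#' supported by family members, pension-supported nonworkers, the unemployed,
#' and children — is `none` with income zero. Pension-supported nonworkers are
#' deliberately `none`: pension incomes enter through matched retirees, not
#' through the fixed allowance.
#'
#' @param persons Person tibble with `household_id`, `employment_status`,
#'   `living_resource`, `age`.
#' @return `persons` with an `earner_group` column added.
#' @export
classify_earner_groups <- function(persons) {
  allowance_hh <- persons |>
    filter(.data$living_resource %in% "basic living allowance") |>
    pull(.data$household_id) |>
    unique()
  persons |>
    mutate(
      earner_group = dplyr::case_when(
        .data$employment_status %in% c("employee", "retiree") &
          .data$household_id %in% allowance_hh ~ "low",
        .data$employment_status %in% c("employee", "retiree") ~ "general",
        .data$employment_status == "nonworking" & .data$age >= 15 &
          .data$living_resource %in%
            c("basic living allowance", "property income", "other") ~ "other",
        TRUE ~ "none"
      )
    )
}

#' Assign the fixed monthly allowance to `other` earners
#'
#' @param persons Persons with an `earner_group` column.
#' @param allowance Monthly allowance in Yuan (default 210, the reported basic
#'   living standard).
#' @return Tibble of income assignments (`person_id`, `earner_group`,
#'   `monthly_income`, `source = "fixed allowance"`), one row per `other`
#'   earner.
#' @export
assign_fixed_incomes <- function(persons, allowance = 210) {
  if (allowance <= 0) abort("`allowance` must be positive.")
  persons |>
    filter(.data$earner_group == "other") |>
    mutate(monthly_income = allowance, source = "fixed allowance") |>
    select("person_id", "earner_group", "monthly_income", "source")
}

# internal: donor/recipient stratum key (sex x matching age group x
# employment status)
income_stratum <- function(records) {
  paste(records$sex, age_group6(records$age), records$employment_status,
        sep = "|")
}

#' Split the insured file into low- and general-income donor pools
#'
#' Per (sex x age group x employment status) cell, `round(ratio * cell size)`
#' insured records are drawn at random into the low-income pool; the rest form
#' the general pool. Ratios default to those observed on the census side, so
#' the donor split mirrors the recipient split.
#'
#' @param insured Insured records tibble.
#' @param ratios Tibble with columns `sex`, `age_group`, `employment_status`,
#'   `ratio` (in `[0, 1]`); missing cells get ratio 0.
#' @param seed Optional seed.
#' @return List of disjoint, exhaustive tibbles `low` and `general`.
#' @export
split_insured_donors <- function(insured, ratios, seed = NULL) {
  if (any(ratios$ratio < 0 | ratios$ratio > 1)) {
    abort("`ratios` must lie in [0, 1].")
  }
  run <- function() {
    keyed <- insured |>
      mutate(.stratum = income_stratum(insured), .row = row_number())
    rat <- ratios |>
      mutate(.stratum = paste(.data$sex, .data$age_group,
                              .data$employment_status, sep = "|"))
    low_rows <- keyed |>
      left_join(select(rat, ".stratum", "ratio"), by = ".stratum") |>
      mutate(ratio = tidyr::replace_na(.data$ratio, 0)) |>
      group_by(.data$.stratum) |>
      dplyr::group_map(function(g, key) {
        k <- round(g$ratio[1] * nrow(g))
        if (k == 0) integer() else sample_vec(g$.row, k)
      }) |>
      unlist()
    low_rows <- low_rows %||% integer()
    list(
      low = insured[sort(low_rows), , drop = FALSE],
      general = insured[setdiff(seq_len(nrow(insured)), low_rows), , drop = FALSE]
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Observed low-earner ratios per matching cell
#'
#' Share of `low` earner-group records among employees/retirees per
#' (sex x age group x employment status) cell on the census side; used as the
#' default donor-split ratios.
#'
#' @param persons Persons with `earner_group`.
#' @return Tibble `sex`, `age_group`, `employment_status`, `ratio`.
#' @export
low_income_cell_ratios <- function(persons) {
  persons |>
    filter(.data$employment_status %in% c("employee", "retiree"),
           .data$age >= 15) |>
    mutate(age_group = age_group6(.data$age)) |>
    group_by(.data$sex, .data$age_group, .data$employment_status) |>
    summarise(ratio = mean(.data$earner_group == "low"), .groups = "drop")
}

#' Impute monthly incomes from a donor pool
#'
#' Each recipient receives the monthly income of a donor drawn at random
#' within its (sex x age group x employment status) stratum; replacement is
#' used only where a stratum has fewer donors than recipients (reported via a
#' message). A recipient stratum with no donors at all falls back to the
#' nearest age group with donors of the same sex and employment status
#' (reported), and errors only if no fallback exists. Donor pools are never
#' modified.
#'
#' @param recipients Tibble with `person_id`, `sex`, `age`,
#'   `employment_status`, and an `earner_group` column copied through.
#' @param donor_pool Tibble with `sex`, `age`, `employment_status`,
#'   `monthly_income`.
#' @param seed Optional seed.
#' @return Tibble of income assignments (`person_id`, `earner_group`,
#'   `monthly_income`, `source = "donor"`).
#' @export
impute_donor_incomes <- function(recipients, donor_pool, seed = NULL) {
  if (nrow(recipients) == 0) {
    return(tibble(person_id = character(), earner_group = character(),
                  monthly_income = numeric(), source = character()))
  }
  if (nrow(donor_pool) == 0) abort("`donor_pool` is empty.")
  run <- function() {
    rs <- income_stratum(recipients)
    ds <- income_stratum(donor_pool)
    out_income <- numeric(nrow(recipients))
    for (s in unique(rs)) {
      ridx <- which(rs == s)
      didx <- which(ds == s)
      if (length(didx) == 0) {
        # fallback chain: nearest age group (same sex, employment), then the
        # other sex, then the other employment status — logged each time
        parts <- strsplit(s, "|", fixed = TRUE)[[1]]
        g <- match(parts[2], pop_levels$age_group6)
        dparts <- do.call(rbind, strsplit(unique(ds), "|", fixed = TRUE))
        cand <- tibble(
          stratum = unique(ds),
          age_dist = abs(match(dparts[, 2], pop_levels$age_group6) - g),
          sex_mis = dparts[, 1] != parts[1],
          emp_mis = dparts[, 3] != parts[3]
        ) |>
          filter(!is.na(.data$age_dist)) |>
          arrange(.data$emp_mis, .data$sex_mis, .data$age_dist)
        if (nrow(cand) == 0) {
          abort(paste0("No donors for stratum ", s, " and no fallback stratum."))
        }
        inform(paste0("Empty donor stratum ", s, "; using donors from ",
                      cand$stratum[1], " instead."))
        didx <- which(ds == cand$stratum[1])
      }
      replace <- length(didx) < length(ridx)
      if (replace) {
        inform(paste0("Stratum ", s, ": ", length(didx), " donors for ",
                      length(ridx), " recipients; sampling with replacement."))
      }
      take <- if (replace) {
        didx[sample.int(length(didx), length(ridx), replace = TRUE)]
      } else {
        sample_vec(didx, length(ridx))
      }
      out_income[ridx] <- donor_pool$monthly_income[take]
    }
    tibble(
      person_id = recipients$person_id,
      earner_group = if ("earner_group" %in% names(recipients))
        recipients$earner_group else NA_character_,
      monthly_income = out_income,
      source = "donor"
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Impute incomes for a whole classified census file
#'
#' Applies the earner-group rules end to end: low earners draw from the low
#' donor pool, general earners from the general pool, `other` earners get the
#' fixed allowance, and `none` persons get zero.
#'
#' @param persons Classified persons (with `earner_group`).
#' @param donors List with `low` and `general` insured donor pools (from
#'   [split_insured_donors()]).
#' @param allowance Fixed monthly allowance for `other` earners.
#' @param seed Optional seed (low and general draws use `seed` and
#'   `seed + 1`).
#' @return `persons` with `monthly_income` and `income_source` columns.
#' @export
impute_all_incomes <- function(persons, donors, allowance = 210, seed = NULL) {
  low_pool <- donors$low
  if (nrow(low_pool) == 0 && any(persons$earner_group == "low")) {
    inform("Low-income donor pool is empty; low earners draw from the general pool.")
    low_pool <- donors$general
  }
  low <- impute_donor_incomes(
    filter(persons, .data$earner_group == "low"), low_pool,
    seed = seed
  )
  general <- impute_donor_incomes(
    filter(persons, .data$earner_group == "general"), donors$general,
    seed = if (is.null(seed)) NULL else seed + 1L
  )
  fixed <- assign_fixed_incomes(persons, allowance)
  assignments <- bind_rows(low, general, fixed) |>
    select("person_id", "monthly_income", "source")
  persons |>
    left_join(assignments, by = "person_id") |>
    mutate(
      monthly_income = dplyr::coalesce(.data$monthly_income, 0),
      income_source = dplyr::coalesce(.data$source, "zero-dependent")
    ) |>
    select(-"source")
}

#' Weighted family-income quintile summary
#'
#' Annual family income is 12 times the sum of members' monthly incomes.
#' Families are ranked by annual income and split into five groups each
#' holding 20% of the total family weight; families are kept whole (a family
#' belongs to the quintile containing its cumulative-weight lower boundary),
#' so realised quintile weights match 20% within one family's weight.
#'
#' @param persons Persons with `household_id`, `monthly_income` and `weight`.
#'   Within a household all members must share one weight (the family weight).
#' @return A `family_income_summary`: tibble with one row per quintile
#'   (`quintile`, `weight_share`, `mean_income`, `min_income`, `max_income`);
#'   attributes `"top_bottom_ratio"` and `"families"` (the per-family table).
#'   [glance()] returns a one-row summary.
#' @export
family_income_quintiles <- function(persons) {
  if (nrow(persons) == 0) abort("`persons` is empty.")
  families <- persons |>
    group_by(.data$household_id) |>
    summarise(
      annual_income = 12 * sum(.data$monthly_income),
      weight = .data$weight[1],
      .groups = "drop"
    ) |>
    arrange(.data$annual_income, .data$household_id)
  total_w <- sum(families$weight)
  if (total_w <= 0) abort("Total family weight must be positive.")
  cum_lower <- cumsum(families$weight) - families$weight
  families$quintile <- pmin(5L, as.integer(floor(5 * cum_lower / total_w)) + 1L)
  qtab <- families |>
    group_by(.data$quintile) |>
    summarise(
      weight_share = sum(.data$weight) / total_w,
      mean_income = weighted.mean(.data$annual_income, .data$weight),
      min_income = min(.data$annual_income),
      max_income = max(.data$annual_income),
      .groups = "drop"
    )
  ratio <- qtab$mean_income[qtab$quintile == 5] /
    qtab$mean_income[qtab$quintile == 1]
  structure(qtab, top_bottom_ratio = ratio, families = families,
            class = c("family_income_summary", class(qtab)))
}

#' @rdname family_income_quintiles
#' @param x,object A `family_income_summary`.
#' @param ... Unused.
#' @method glance family_income_summary
#' @export
glance.family_income_summary <- function(x, ...) {
  tibble(
    n_families = nrow(attr(x, "families")),
    middle_quintile_income = x$mean_income[x$quintile == 3],
    top_bottom_ratio = attr(x, "top_bottom_ratio")
  )
}

#' @rdname family_income_quintiles
#' @method autoplot family_income_summary
#' @export
autoplot.family_income_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$quintile), y = .data$mean_income)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "family income quintile", y = "mean annual income (Yuan)")
}

#' Weighted mean annual disposable income per person
#'
#' @param persons Persons with `monthly_income` and `weight`.
#' @return Scalar: weighted mean of `12 * monthly_income`, Yuan per year.
#' @export
#' @examples
#' mean_disposable_income(tibble::tibble(monthly_income = 1000, weight = 1))
mean_disposable_income <- function(persons) {
  weighted.mean(12 * persons$monthly_income, persons$weight)
}
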