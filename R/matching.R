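# Statistical matching of the insured administrative file onto the census
# file: assemble the insured population, sample it down to census-sample
# scale, stratify both sides into cell groups (sex x age group x employment x
# marital status), resolve per-cell deficits, pair within cells by minimal
# age distance, and adjust weights onto target subpopulation totals.

cell_key_vars <- c("sex", "age_group", "employment_status", "marital_status")

# internal: full 72-cell key grid
cell_key_grid <- function() {
  tidyr::expand_grid(
    sex = pop_levels$sex,
    age_group = pop_levels$age_group6,
    employment_status = c("employee", "retiree"),
    marital_status = pop_levels$marital_status
  )
}

# internal: attach the matching cell key; records under 15 get NA age_group
with_cell_key <- function(records) {
  mutate(records, age_group = age_group6(.data$age))
}

#' Assemble the full insured population from the municipal file
#'
#' The administrative file only covers municipally administered participants;
#' provincially administered participants and senior retirees have no
#' individual records, so they are imputed as random clones of municipal
#' records. Senior clones are drawn only from donors older than
#' `senior_age_floor` (68 by default: the senior-retiree cohort's reported
#' ages start above that). Draws are without replacement unless the donor pool
#' is smaller than the request, in which case replacement is used and a
#' message is emitted.
#'
#' @param municipal Tibble of municipal insured records (needs `record_id`,
#'   `age`; other columns are carried along).
#' @param provincial_count,senior_count Numbers of records to clone.
#' @param senior_age_floor Senior donors must be strictly older than this.
#' @param seed Optional seed for the clone draws.
#' @return Tibble of `nrow(municipal) + provincial_count + senior_count`
#'   records with a `stratum` column set to municipal/provincial/senior and
#'   fresh `record_id`s for clones.
#' @export
assemble_insured_population <- function(municipal, provincial_count,
                                        senior_count, senior_age_floor = 68,
                                        seed = NULL) {
  if (nrow(municipal) == 0) abort("`municipal` must be nonempty.")
  stopifnot(provincial_count >= 0, senior_count >= 0)
  run <- function() {
    draw <- function(pool, k, label) {
      if (k == 0) return(pool[0, ])
      replace <- k > nrow(pool)
      if (replace) {
        inform(paste0("Donor pool (", nrow(pool), ") smaller than ", label,
                      " request (", k, "); drawing with replacement."))
      }
      slice_sample(pool, n = k, replace = replace)
    }
    prov <- draw(municipal, provincial_count, "provincial") |>
      mutate(stratum = "provincial")
    senior_pool <- filter(municipal, .data$age > senior_age_floor)
    if (senior_count > 0 && nrow(senior_pool) == 0) {
      abort(paste0("No donors older than ", senior_age_floor,
                   " for the senior stratum."))
    }
    sen <- draw(senior_pool, senior_count, "senior") |>
      mutate(stratum = "senior")
    out <- bind_rows(mutate(municipal, stratum = "municipal"), prov, sen)
    mutate(out, record_id = sprintf("M%07d", row_number()))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Matching-sample size implied by an average weight
#'
#' The matching sample of insured records should represent its population at
#' the census file's sampling fraction, so the sample count is the population
#' divided by the census side's average weight for that group.
#'
#' @param population Group population count.
#' @param average_weight Average census weight of the group (> 0).
#' @return Integer sample size, `round(population / average_weight)`.
#' @export
#' @examples
#' stratum_sample_size(4403, 12.542439139) # 351
stratum_sample_size <- function(population, average_weight) {
  if (average_weight <= 0) abort("`average_weight` must be positive.")
  stopifnot(population >= 0)
  as.integer(round(population / average_weight))
}

#' Tabulate records into matching cell groups
#'
#' Crosses sex (2) x age group (6: 15-24 ... 65+) x employment status
#' (employee/retiree) x marital status (3): 72 cells. Records younger than 15
#' are excluded (they are never matched) and their count reported; empty cells
#' are kept with a zero count, since in practice some combinations (young
#' retirees) do not occur.
#'
#' @param records Tibble with `sex`, `age`, `employment_status`,
#'   `marital_status`.
#' @return Tibble of 72 rows (`sex`, `age_group`, `employment_status`,
#'   `marital_status`, `n`); attribute `"excluded"` counts dropped under-15
#'   records.
#' @export
tabulate_cells <- function(records) {
  excluded <- sum(records$age < 15)
  if (excluded > 0) {
    inform(paste0(excluded, " record(s) under age 15 excluded from cell tabulation."))
  }
  keyed <- records |>
    filter(.data$age >= 15,
           .data$employment_status %in% c("employee", "retiree")) |>
    with_cell_key()
  out <- keyed |>
    count(.data$sex, .data$age_group, .data$employment_status,
          .data$marital_status) |>
    full_join(cell_key_grid(),
              by = cell_key_vars) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(.data$sex, .data$age_group, .data$employment_status,
            .data$marital_status)
  attr(out, "excluded") <- excluded
  out
}

#' Resolve per-cell matching deficits
#'
#' Within each cell the census side must offer at least as many records as the
#' insured side demands. Cells where demand exceeds supply have their surplus
#' demand moved to the closest cell with slack, closeness being lexicographic:
#' smallest age-group distance first, then same marital status, then same sex.
#' Every move is logged in the `"moves"` attribute.
#'
#' @param census_counts,insured_counts Cell-count tibbles from
#'   [tabulate_cells()] (column `n`).
#' @return Tibble of per-cell quotas (`quota <= census n`, total preserved);
#'   attribute `"moves"` is a tibble of from/to cells and moved counts.
#' @export
resolve_deficits <- function(census_counts, insured_counts) {
  grid <- census_counts |>
    rename(census = "n") |>
    left_join(rename(insured_counts, insured = "n"), by = cell_key_vars) |>
    mutate(insured = tidyr::replace_na(.data$insured, 0L))
  if (sum(grid$insured) > sum(grid$census)) {
    abort("Total insured demand exceeds total census supply; matching is infeasible.")
  }
  quota <- pmin(grid$insured, grid$census)
  surplus <- grid$insured - quota
  age_idx <- match(grid$age_group, pop_levels$age_group6)
  moves <- list()
  for (i in which(surplus > 0)) {
    need <- surplus[i]
    # lexicographic closeness: same employment status above all, then the
    # smallest age-group distance, then same marital status, then same sex
    dist <- abs(age_idx - age_idx[i]) * 4 +
      (grid$marital_status != grid$marital_status[i]) * 2 +
      (grid$sex != grid$sex[i]) * 1 +
      (grid$employment_status != grid$employment_status[i]) * 100
    for (j in order(dist)) {
      if (j == i || need == 0) next
      slack <- grid$census[j] - quota[j]
      if (slack <= 0) next
      take <- min(slack, need)
      quota[j] <- quota[j] + take
      need <- need - take
      moves[[length(moves) + 1]] <- tibble(
        from = paste(grid[i, cell_key_vars], collapse = "|"),
        to = paste(grid[j, cell_key_vars], collapse = "|"),
        moved = take
      )
      if (need == 0) break
    }
    if (need > 0) abort("Could not place all surplus demand; matching is infeasible.")
  }
  out <- grid |> mutate(quota = quota) |> select(-"census", -"insured")
  attr(out, "moves") <- if (length(moves)) bind_rows(moves) else
    tibble(from = character(), to = character(), moved = integer())
  out
}

#' Draw the census-side counterpart sample
#'
#' Randomly selects, per cell, the quota of census records that will be
#' matched against the insured sample.
#'
#' @param census Census person tibble (employees/retirees aged 15+ are
#'   eligible).
#' @param quotas Quota tibble from [resolve_deficits()].
#' @param seed Optional seed.
#' @return Tibble of selected census records with the cell key attached.
#' @export
draw_counterparts <- function(census, quotas, seed = NULL) {
  run <- function() {
    keyed <- census |>
      filter(.data$age >= 15,
             .data$employment_status %in% c("employee", "retiree")) |>
      with_cell_key()
    keyed |>
      dplyr::inner_join(quotas, by = cell_key_vars) |>
      group_by(dplyr::across(dplyr::all_of(cell_key_vars))) |>
      dplyr::group_modify(~ slice_sample(.x, n = .x$quota[1])) |>
      ungroup() |>
      select(-"quota")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Distance specification for within-cell matching
#'
#' The matching distance is a weighted, variance-scaled squared difference
#' summed over the matching variables, with variances computed from the census
#' side. With the default single variable (age) the importance weight and
#' variance cancel and the distance reduces to the absolute age difference, in
#' which case sorting both sides by age and pairing by rank minimises the
#' total distance exactly.
#'
#' @param variables Matching variables (numeric columns present on both
#'   sides). Default `"age"`.
#' @param importance Positive importance weights, one per variable.
#' @param variances Optional positive variances, one per variable; computed
#'   from the census side when omitted.
#' @return A list of class `distance_spec`.
#' @export
distance_spec <- function(variables = "age",
                          importance = rep(1, length(variables)),
                          variances = NULL) {
  stopifnot(length(importance) == length(variables), all(importance > 0))
  if (!is.null(variances)) {
    stopifnot(length(variances) == length(variables), all(variances > 0))
  }
  structure(list(variables = variables, importance = importance,
                 variances = variances),
            class = "distance_spec")
}

#' Matching distance between records
#'
#' @param x_mip,x_cp Numeric matrices (or vectors for one variable) of
#'   matching-variable values for insured and census records.
#' @param spec A [distance_spec()]; `variances` must be set (it is filled in
#'   by [match_within_cells()]).
#' @return Numeric vector of distances.
#' @export
matching_distance <- function(x_mip, x_cp, spec) {
  x_mip <- as.matrix(x_mip); x_cp <- as.matrix(x_cp)
  v <- spec$variances %||% rep(1, length(spec$variables))
  rowSums(sweep((x_mip - x_cp)^2, 2, spec$importance / v, `*`))
}

#' Match insured and census records within cell groups
#'
#' Requires equal record counts per cell on both sides (arrange this with
#' [resolve_deficits()] and [draw_counterparts()]). With the default
#' single-variable specification both sides are sorted by age (ties broken by
#' record id for determinism) and paired by rank, which minimises the total
#' absolute age difference. With several matching variables a greedy
#' nearest-neighbour pairing on the variance-scaled distance is used instead
#' (a heuristic; the single-variable case remains the canonical configuration).
#'
#' @param insured_sample Insured records (`record_id`, `age`, cell-key
#'   columns, `monthly_income`, `stratum`).
#' @param census_sample Census records (`person_id`, `age`, cell-key columns).
#' @param spec A [distance_spec()].
#' @return A `match_result`: tibble of matched pairs (`person_id`,
#'   `record_id`, cell key, both ages, `age_gap`, transferred
#'   `monthly_income`/`stratum`), with summary statistics (mean gap, max gap,
#'   share of gaps under 4 years) in the `"summary"` attribute and available
#'   via [glance()].
#' @export
match_within_cells <- function(insured_sample, census_sample,
                               spec = distance_spec()) {
  ins <- with_cell_key(insured_sample)
  cen <- with_cell_key(census_sample)
  ins$.cell <- do.call(paste, c(ins[cell_key_vars], sep = "|"))
  cen$.cell <- do.call(paste, c(cen[cell_key_vars], sep = "|"))
  ci <- table(ins$.cell); cc <- table(cen$.cell)
  all_cells <- union(names(ci), names(cc))
  ni <- as.integer(ci[all_cells]); ni[is.na(ni)] <- 0L
  nc <- as.integer(cc[all_cells]); nc[is.na(nc)] <- 0L
  if (any(ni != nc)) {
    bad <- all_cells[which(ni != nc)[1]]
    abort(paste0("Cell ", bad, " has ", ni[ni != nc][1], " insured vs ",
                 nc[ni != nc][1], " census records; counts must be equal."))
  }
  if (is.null(spec$variances)) {
    v <- purrr::map_dbl(spec$variables, \(nm) {
      vv <- var(census_sample[[nm]])
      if (!is.finite(vv) || vv == 0) 1 else vv
    })
    spec$variances <- v
  }
  single <- length(spec$variables) == 1

  pairs <- purrr::map(sort(unique(ins$.cell)), function(cl) {
    a <- ins[ins$.cell == cl, ]
    b <- cen[cen$.cell == cl, ]
    if (single) {
      a <- a[order(a[[spec$variables]], a$record_id), ]
      b <- b[order(b[[spec$variables]], b$person_id), ]
      idx <- seq_len(nrow(a))
    } else {
      dm <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
                  Vectorize(function(i, j) {
                    matching_distance(a[i, spec$variables],
                                      b[j, spec$variables], spec)
                  }))
      idx <- integer(nrow(a))
      freeb <- rep(TRUE, nrow(b))
      for (i in seq_len(nrow(a))) {
        j <- which(freeb)[which.min(dm[i, freeb])]
        idx[i] <- j; freeb[j] <- FALSE
      }
    }
    tibble(
      person_id = b$person_id[idx],
      record_id = a$record_id,
      sex = a$sex, age_group = a$age_group,
      employment_status = a$employment_status,
      marital_status = a$marital_status,
      insured_age = a$age, census_age = b$age[idx],
      age_gap = abs(a$age - b$age[idx]),
      monthly_income = if ("monthly_income" %in% names(a)) a$monthly_income else NA_real_,
      stratum = if ("stratum" %in% names(a)) a$stratum else NA_character_
    )
  }) |> bind_rows()

  summary <- tibble(
    n_pairs = nrow(pairs),
    mean_age_gap = mean(pairs$age_gap),
    max_age_gap = if (nrow(pairs)) max(pairs$age_gap) else NA_real_,
    share_gap_lt4 = mean(pairs$age_gap < 4)
  )
  structure(pairs, summary = summary, class = c("match_result", class(pairs)))
}

#' @rdname match_within_cells
#' @param x,object A `match_result`.
#' @param ... Unused.
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) attr(x, "summary")

#' @rdname match_within_cells
#' @method autoplot match_result
#' @export
autoplot.match_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$age_gap)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0) +
    ggplot2::labs(x = "age gap of matched pair (years)", y = "pairs")
}

#' Rescale group weights onto a target population
#'
#' Multiplies every weight by `target_population / current weighted total`, so
#' the group's weighted total hits the target exactly. Used after matching to
#' pull subpopulations (e.g. the declining senior-retiree cohort) onto their
#' projected totals.
#'
#' @param records Tibble with a `weight` column.
#' @param target_population Target weighted total (> 0 unless the group is
#'   empty).
#' @return `records` with adjusted `weight`; the scalar coefficient is in the
#'   `"coefficient"` attribute.
#' @export
#' @examples
#' r <- tibble::tibble(weight = c(2, 3))
#' sum(adjust_weights(r, 10)$weight) # 10
adjust_weights <- function(records, target_population) {
  current <- sum(records$weight)
  if (current <= 0) abort("Current weighted total must be positive.")
  coef <- target_population / current
  out <- mutate(records, weight = .data$weight * coef)
  attr(out, "coefficient") <- coef
  out
}
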