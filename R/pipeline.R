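# End-to-end orchestration: generate -> clone -> calibrate -> project ->
# match -> impute incomes -> report, with per-stage seeds and stage toggles.

#' Run configuration for the full pipeline
#'
#' @param seed Master seed; per-stage seeds are derived as small fixed offsets
#'   so every stage is independently reproducible.
#' @param synthetic A [synthetic_config()]; its seed is overridden by the
#'   derived generate-stage seed.
#' @param copies Clone copies for the census sample.
#' @param base_population Population the cloned sample represents (the
#'   2000-census total by default).
#' @param years Target years (subset of 2005:2010); matching and income run at
#'   the first year, group tables are produced for all of them.
#' @param calibration List of calibration settings (`bounds`, `tolerance`,
#'   `max_iterations`, `household_integrated`).
#' @param allowance Fixed monthly allowance for `other` earners (Yuan).
#' @param senior_target_factor Per-year multiplicative decline applied to the
#'   senior-retiree weighted total after matching (the cohort shrinks because
#'   of its age); 1 leaves senior weights untouched.
#' @param stages Character vector of stages to run, in order, from
#'   `c("generate", "clone", "calibrate", "match", "impute", "report")`.
#'   Stages after the first disabled one are skipped too.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       synthetic = synthetic_config(),
                       copies = 3L,
                       base_population = 5781300,
                       years = 2005,
                       calibration = list(bounds = c(0.1, 10),
                                          tolerance = 1e-6,
                                          max_iterations = 50L,
                                          household_integrated = TRUE),
                       allowance = 210,
                       senior_target_factor = 0.9,
                       stages = c("generate", "clone", "calibrate", "match",
                                  "impute", "report")) {
  stopifnot(all(years %in% 2005:2010),
            all(stages %in% c("generate", "clone", "calibrate", "match",
                              "impute", "report")))
  structure(
    list(seed = as.integer(seed), synthetic = synthetic, copies = copies,
         base_population = base_population, years = sort(years),
         calibration = calibration, allowance = allowance,
         senior_target_factor = senior_target_factor, stages = stages),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()] and the
#' scalar arguments of [synthetic_config()] (under `synthetic:`). Unknown keys
#' raise an error so typos never pass silently.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "synthetic", "copies", "base_population", "years",
             "calibration", "allowance", "senior_target_factor", "stages")
  extra <- setdiff(names(raw), known)
  if (length(extra)) abort(paste0("Unknown config keys: ",
                                  paste(extra, collapse = ", ")))
  syn <- if (!is.null(raw$synthetic)) do.call(synthetic_config, raw$synthetic)
         else synthetic_config()
  args <- raw[setdiff(names(raw), "synthetic")]
  args$synthetic <- syn
  do.call(run_config, args)
}

# internal: named per-stage seeds derived from the master seed
stage_seeds <- function(seed) {
  c(generate = seed, clone = seed + 101L, calibrate = seed + 202L,
    match = seed + 303L, impute = seed + 404L)
}

#' Classify persons into medical-insurance population groups
#'
#' Every person gets exactly one of: insured employee, insured retiree,
#' uninsured employee, uninsured unemployed, uninsured retiree, or resident
#' out of the labour force. Residents are further split into adults (18+),
#' children (<18) and university students, each either general or concession
#' (disabled, or member of a family receiving the basic living allowance).
#'
#' @param persons Persons with `employment_status`, `insured` (logical), `age`,
#'   `student`, `disabled`, `household_id`, `living_resource`.
#' @return `persons` with `population_group` and, for residents,
#'   `resident_category` (`adult`/`child`/`university student`) and
#'   `resident_status` (`general`/`concession`) columns.
#' @export
classify_population_groups <- function(persons) {
  allowance_hh <- persons |>
    filter(.data$living_resource %in% "basic living allowance") |>
    pull(.data$household_id) |>
    unique()
  out <- persons |>
    mutate(
      population_group = dplyr::case_when(
        .data$employment_status == "employee" & .data$insured ~ "insured employee",
        .data$employment_status == "retiree" & .data$insured ~ "insured retiree",
        .data$employment_status == "employee" ~ "uninsured employee",
        .data$employment_status == "retiree" ~ "uninsured retiree",
        .data$employment_status == "unemployed" ~ "uninsured unemployed",
        .data$employment_status %in% c("nonworking", "child") ~ "resident",
        TRUE ~ NA_character_
      )
    )
  if (any(is.na(out$population_group))) {
    bad <- out$person_id[which(is.na(out$population_group))[1]]
    abort(paste0("Record ", bad, " cannot be assigned a population group."))
  }
  out |>
    mutate(
      resident_category = if_else(
        .data$population_group == "resident",
        dplyr::case_when(
          .data$age < 18 ~ "child",
          .data$student & .data$education == "tertiary" ~ "university student",
          TRUE ~ "adult"
        ),
        NA_character_
      ),
      resident_status = if_else(
        .data$population_group == "resident",
        if_else(.data$disabled | .data$household_id %in% allowance_hh,
                "concession", "general"),
        NA_character_
      )
    )
}

# internal: weighted population structure by benchmark dimension
structure_table <- function(persons, year) {
  vals <- persons |>
    mutate(age_group = age_group8(.data$age)) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("sex", "age_group", "residential_status",
                             "nationality", "education")),
      names_to = "dimension", values_to = "category"
    ) |>
    group_by(.data$dimension, .data$category) |>
    summarise(population = sum(.data$weight), .groups = "drop")
  vals |>
    group_by(.data$dimension) |>
    mutate(year = year, share = 100 * .data$population / sum(.data$population)) |>
    ungroup() |>
    select("year", "dimension", "category", "population", "share")
}

# internal: weighted population-group table with shares summing to 100
group_table <- function(persons, year) {
  persons |>
    group_by(.data$population_group) |>
    summarise(population = sum(.data$weight), .groups = "drop") |>
    mutate(year = year, share = 100 * .data$population / sum(.data$population)) |>
    select("year", "population_group", "population", "share")
}

# internal: resident breakdown (category x status)
resident_table <- function(persons, year) {
  persons |>
    filter(.data$population_group == "resident") |>
    group_by(.data$resident_category, .data$resident_status) |>
    summarise(population = sum(.data$weight), .groups = "drop") |>
    mutate(year = year, share = 100 * .data$population / sum(.data$population)) |>
    select("year", "resident_category", "resident_status", "population", "share")
}

#' Run the full microsimulation pipeline
#'
#' Executes the enabled stages in order on synthetic data: generate the census
#' sample and insured file, clone the sample, calibrate weights to each target
#' year's benchmarks (the published table for 2005 and 2010, projected tables
#' otherwise), statistically match the insured file onto the first target
#' year's census file, impute incomes, and assemble report tables. The run is
#' end-to-end deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `population_groups` and
#'   `residents` tibbles (one row set per year), `income_quintiles`,
#'   `mean_disposable_income`, `match_quality`, `calibration` (per-year
#'   [glance()] rows), `seeds`, `persons` (the final matched, classified,
#'   income-bearing person file for the first year) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)
  stages <- config$stages
  on <- function(s) s %in% stages

  # --- generate -------------------------------------------------------------
  syn <- config$synthetic
  syn$seed <- seeds[["generate"]]
  sample <- generate_census_sample(syn)
  insured <- generate_insured_file(syn, sample$persons)

  report <- list(seeds = seeds, config = config)
  persons <- sample$persons
  if (!on("clone")) {
    report$persons <- persons
    return(structure(report, class = "run_report"))
  }

  # --- clone ----------------------------------------------------------------
  cloned <- clone_sample(persons, config$copies, config$base_population)
  insured_cloned <- withr::with_seed(seeds[["clone"]], {
    # the administrative file scales with the census sample it was drawn from
    clone_sample(mutate(insured, household_id = .data$record_id,
                        person_id = .data$record_id, weight = 1),
                 config$copies, nrow(insured) * (config$copies + 1)) |>
      mutate(record_id = .data$person_id) |>
      select(-"household_id", -"weight")
  })

  if (!on("calibrate")) {
    report$persons <- cloned
    return(structure(report, class = "run_report"))
  }

  # --- calibrate (per year) -------------------------------------------------
  cal <- config$calibration
  benchmarks <- purrr::map(config$years, function(y) {
    if (y %in% c(2005, 2010)) return(benchmark_fixture(y))
    bm05 <- benchmark_fixture(2005)
    total10 <- project_total(
      bm05$total[bm05$dimension == "total"],
      rate_2010(growth_model())$rate, 5, nearest_ten = TRUE
    )
    build_benchmarks(bm05, structure_assumptions(), total10, years = y) |>
      select("year", "dimension", "category", "total")
  }) |> setNames(as.character(config$years))

  calibrated <- purrr::map(benchmarks, function(bm) {
    calibrate_to_benchmark(
      cloned, bm,
      household_integrated = isTRUE(cal$household_integrated),
      bounds = cal$bounds %||% c(0.1, 10),
      tolerance = cal$tolerance %||% 1e-6,
      max_iterations = cal$max_iterations %||% 50L
    )
  })
  report$calibration <- purrr::imap(calibrated, \(c, y)
    mutate(glance(c$result), year = as.integer(y), .before = 1)) |> bind_rows()
  report$population_structure <- purrr::imap(calibrated, \(c, y)
    structure_table(c$persons, as.integer(y))) |> bind_rows()

  year1 <- as.character(config$years[1])
  persons1 <- calibrated[[year1]]$persons

  if (!on("match")) {
    report$persons <- persons1
    report$population_groups <- NULL
    return(structure(report, class = "run_report"))
  }

  # --- match ----------------------------------------------------------------
  ins_cells <- suppressMessages(tabulate_cells(insured_cloned))
  cen_cells <- suppressMessages(tabulate_cells(persons1))
  quotas <- resolve_deficits(cen_cells, ins_cells)
  counterparts <- draw_counterparts(persons1, quotas, seed = seeds[["match"]])
  matches <- match_within_cells(insured_cloned, counterparts)
  report$match_quality <- glance(matches)

  persons1 <- persons1 |>
    left_join(
      select(as_tibble(matches), "person_id", matched_income = "monthly_income",
             "stratum"),
      by = "person_id"
    ) |>
    mutate(insured = !is.na(.data$stratum))

  # senior weighted total declines with the cohort's age
  if (config$senior_target_factor != 1 && any(persons1$stratum %in% "senior")) {
    seniors <- filter(persons1, .data$stratum %in% "senior")
    target <- config$senior_target_factor * sum(seniors$weight)
    adjusted <- adjust_weights(seniors, target)
    persons1$weight[match(adjusted$person_id, persons1$person_id)] <-
      adjusted$weight
  }

  if (!on("impute")) {
    report$persons <- persons1
    return(structure(report, class = "run_report"))
  }

  # --- impute incomes -------------------------------------------------------
  persons1 <- classify_earner_groups(persons1)
  ratios <- low_income_cell_ratios(persons1)
  donors <- split_insured_donors(insured_cloned, ratios,
                                 seed = seeds[["impute"]])
  persons1 <- suppressMessages(impute_all_incomes(
    persons1, donors, allowance = config$allowance,
    seed = seeds[["impute"]] + 1L
  ))
  report$income_quintiles <- family_income_quintiles(persons1)
  report$mean_disposable_income <- mean_disposable_income(persons1)

  # --- report ---------------------------------------------------------------
  persons1 <- classify_population_groups(persons1)
  report$persons <- persons1
  if (on("report")) {
    group_tabs <- purrr::imap(calibrated, function(c, y) {
      p <- c$persons |>
        left_join(select(persons1, "person_id", "insured", "population_group",
                         "resident_category", "resident_status"),
                  by = "person_id")
      list(groups = group_table(p, as.integer(y)),
           residents = resident_table(p, as.integer(y)))
    })
    report$population_groups <- purrr::map(group_tabs, "groups") |> bind_rows()
    report$residents <- purrr::map(group_tabs, "residents") |> bind_rows()
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$population_groups)) {
    cat("population groups:\n")
    print(as.data.frame(x$population_groups), row.names = FALSE)
  }
  if (!is.null(x$match_quality)) {
    cat("match quality:\n")
    print(as.data.frame(x$match_quality), row.names = FALSE)
  }
  if (!is.null(x$mean_disposable_income)) {
    cat("mean disposable income (Yuan/yr):",
        round(x$mean_disposable_income, 2), "\n")
  }
  invisible(x)
}

#' Plot weighted age-group shares across target years
#'
#' The classic ageing-population picture: one line per age group, share of the
#' calibrated population by year.
#'
#' @param report A `run_report` from [run_pipeline()] (needs the calibrate
#'   stage).
#' @return A ggplot.
#' @export
plot_age_trends <- function(report) {
  stopifnot(inherits(report, "run_report"),
            !is.null(report$population_structure))
  df <- filter(report$population_structure, .data$dimension == "age_group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$share,
                                   colour = .data$category,
                                   group = .data$category)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "share of population (%)", colour = "age group")
}

#' Write the report tables of a pipeline run
#'
#' Tables go to CSV, scalar summaries to a single JSON file.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) utils::write.csv(as_tibble(df),
                                       file.path(dir, paste0(name, ".csv")),
                                       row.names = FALSE)
  }
  w(report$population_groups, "population_groups")
  w(report$residents, "residents")
  w(report$income_quintiles, "income_quintiles")
  w(report$calibration, "calibration")
  summaries <- list(
    mean_disposable_income = report$mean_disposable_income,
    match_quality = report$match_quality,
    seeds = as.list(report$seeds)
  )
  jsonlite::write_json(summaries, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
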