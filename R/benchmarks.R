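#' Published benchmark tables for 2000, 2005 and 2010
#'
#' Returns the published population distribution for the supported years as a
#' benchmark table: the grand total plus category totals for the five
#' calibration dimensions (sex, eight age groups, residential status,
#' nationality, education including the under-6 row). Totals are printed to
#' the nearest ten, so a dimension's categories may miss the grand total by a
#' few tens; [reconcile_benchmark()] removes that rounding slack before
#' calibration.
#'
#' @param year One of 2000, 2005, 2010. Other years are not published; build
#'   them with [build_benchmarks()] in the projection step.
#' @return A tibble with columns `year`, `dimension`, `category`, `total`.
#' @export
#' @examples
#' benchmark_fixture(2005)
benchmark_fixture <- function(year) {
  stopifnot(length(year) == 1, is.numeric(year))
  if (!year %in% c(2000, 2005, 2010)) {
    abort(paste0(
      "No published benchmark table for year ", year,
      "; use build_benchmarks() to project one from the 2005 base."
    ))
  }
  path <- system.file("extdata", "benchmarks_table1.csv", package = "popfusion",
                      mustWork = TRUE)
  all <- as_tibble(read.csv(path, check.names = FALSE))
  out <- filter(all, .data$year == !!year)
  validate_benchmark(out)
  out
}

#' Validate a benchmark table
#'
#' Checks the structural invariants: non-negative totals, a single `total`
#' row, and each dimension's categories summing to the grand total within the
#' rounding slack of published tables (5 per category, totals printed to the
#' nearest ten).
#'
#' @param benchmark A tibble with columns `dimension`, `category`, `total`
#'   (and optionally `year`).
#' @param rounding_slack Permitted absolute deviation per category between a
#'   dimension's sum and the grand total.
#' @return The table, invisibly; errors on violation.
#' @export
validate_benchmark <- function(benchmark, rounding_slack = 5) {
  need <- c("dimension", "category", "total")
  if (!all(need %in% names(benchmark))) {
    abort("Benchmark table needs columns dimension, category, total.")
  }
  if (any(benchmark$total < 0)) abort("Benchmark totals must be >= 0.")
  grand <- benchmark$total[benchmark$dimension == "total"]
  if (length(grand) != 1) abort("Benchmark table needs exactly one `total` row.")
  sums <- benchmark |>
    filter(.data$dimension != "total") |>
    group_by(.data$dimension) |>
    summarise(s = sum(.data$total), k = dplyr::n(), .groups = "drop")
  bad <- abs(sums$s - grand) > rounding_slack * sums$k
  if (any(bad)) {
    abort(paste0("Dimension(s) ", paste(sums$dimension[bad], collapse = ", "),
                 " do not sum to the grand total within rounding."))
  }
  invisible(benchmark)
}

#' Reconcile a benchmark table to its grand total
#'
#' Published category totals are rounded to the nearest ten, so each
#' dimension's categories can miss the grand total by a few tens. Calibration
#' constraints must be exactly consistent, so each dimension is rescaled
#' proportionally onto the grand total. Adjustments are recorded in the
#' `"adjustments"` attribute (one row per dimension with the scale factor).
#'
#' @inheritParams validate_benchmark
#' @return The reconciled table; attribute `"adjustments"` holds a tibble of
#'   per-dimension scale factors.
#' @export
reconcile_benchmark <- function(benchmark) {
  validate_benchmark(benchmark)
  grand <- benchmark$total[benchmark$dimension == "total"]
  adj <- benchmark |>
    filter(.data$dimension != "total") |>
    group_by(.data$dimension) |>
    summarise(scale = grand / sum(.data$total), .groups = "drop")
  out <- benchmark |>
    left_join(adj, by = "dimension") |>
    mutate(total = .data$total * dplyr::coalesce(.data$scale, 1)) |>
    select(-"scale")
  attr(out, "adjustments") <- adj
  out
}

#' Benchmark shares by dimension
#'
#' @inheritParams validate_benchmark
#' @return Tibble with a `share` column (per cent of the grand total), the
#'   `total` row dropped.
#' @export
benchmark_shares <- function(benchmark) {
  grand <- benchmark$total[benchmark$dimension == "total"]
  benchmark |>
    filter(.data$dimension != "total") |>
    mutate(share = 100 * .data$total / grand)
}

#' Read / write benchmark tables as CSV
#'
#' The on-disk schema is `year,dimension,category,total`, the same schema the
#' shipped published fixture uses.
#'
#' @param path File path.
#' @return `read_benchmark()` returns a validated tibble.
#' @export
read_benchmark <- function(path) {
  out <- as_tibble(read.csv(path, check.names = FALSE))
  validate_benchmark(out)
  out
}

#' @rdname read_benchmark
#' @param benchmark Benchmark table to write.
#' @export
write_benchmark <- function(benchmark, path) {
  validate_benchmark(benchmark)
  utils::write.csv(benchmark, path, row.names = FALSE)
  invisible(path)
}
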