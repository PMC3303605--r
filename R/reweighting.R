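# Static ageing: clone the base sample to increase heterogeneity, then
# calibrate weights to benchmark tables with a bounded chi-square (GREG)
# estimator, optionally integrated so all members of a household share one
# weight.

#' Clone a household-structured sample
#'
#' Replicates every record `copies` additional times, keeping household
#' structures intact but giving each clone fresh household and person ids, and
#' sets every weight to `target_population / (n * (copies + 1))`. Cloning a
#' 0.095% census sample 115 times yields roughly a 10% sample: instead of one
#' person with weight ~116w there are 116 persons with weight ~w, each able to
#' carry a different matched insurance status downstream.
#'
#' @param persons Person tibble with `person_id`, `household_id`, `weight`.
#' @param copies Number of additional copies (>= 0); `copies = 0` only resets
#'   the weights.
#' @param target_population Population the cloned sample represents.
#' @return The cloned tibble; clone `k` has ids suffixed `_ck`.
#' @export
#' @examples
#' p <- tibble::tibble(person_id = "P1", household_id = "H1", weight = 1)
#' clone_sample(p, copies = 2, target_population = 300)
clone_sample <- function(persons, copies, target_population) {
  if (nrow(persons) == 0) abort("Cannot clone an empty sample.")
  stopifnot(copies >= 0, target_population > 0)
  copies <- as.integer(copies)
  out <- purrr::map(0:copies, function(k) {
    if (k == 0) return(persons)
    mutate(persons,
           person_id = paste0(.data$person_id, "_c", k),
           household_id = paste0(.data$household_id, "_c", k))
  }) |> bind_rows()
  mutate(out, weight = target_population / nrow(out))
}

#' Build the calibration indicator matrix
#'
#' One column per benchmark category (including the grand total): entry
#' `[i, j]` is 1 iff person `i` contributes to category `j`. The five
#' dimensions are linearly dependent (each dimension's columns sum to the
#' total column), so the returned object also identifies a maximal linearly
#' independent column subset, found by a pivoted decomposition of the
#' cross-product matrix; the solver uses the kept columns and residuals are
#' still reported for every category.
#'
#' @param persons Person tibble with `sex`, `age`, `residential_status`,
#'   `nationality`, `education` columns.
#' @param benchmark Benchmark table giving the categories (and targets).
#' @return A list of class `indicator_matrix`: `x` (n x p 0/1 matrix, all
#'   columns), `targets` (named vector aligned with columns), `keep` (logical,
#'   independent columns), `dropped` (names of redundant columns).
#' @export
build_indicator_matrix <- function(persons, benchmark) {
  validate_benchmark(benchmark)
  dims <- list(
    sex = persons$sex,
    age_group = age_group8(persons$age),
    residential_status = persons$residential_status,
    nationality = persons$nationality,
    education = persons$education
  )
  n <- nrow(persons)
  bm <- filter(benchmark, .data$dimension != "total")
  cols <- c("total:total", paste(bm$dimension, bm$category, sep = ":"))
  targets <- setNames(
    c(benchmark$total[benchmark$dimension == "total"], bm$total), cols
  )
  x <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  x[, "total:total"] <- 1
  for (j in seq_len(nrow(bm))) {
    d <- bm$dimension[j]
    if (!d %in% names(dims)) abort(paste0("Unknown benchmark dimension: ", d))
    x[, j + 1] <- as.numeric(dims[[d]] == bm$category[j])
  }
  # unmapped categories: a person must land in exactly one category per dim
  for (d in unique(bm$dimension)) {
    cat_cols <- which(bm$dimension == d) + 1
    hits <- rowSums(x[, cat_cols, drop = FALSE])
    if (any(hits != 1)) {
      i <- which(hits != 1)[1]
      abort(paste0("Record ", persons$person_id[i] %||% i, ": value '",
                   dims[[d]][i], "' in field '", d,
                   "' does not map to any benchmark category."))
    }
  }
  # independent columns via pivoted QR of the cross-product
  cp <- crossprod(x)
  qrd <- qr(cp)
  keep <- logical(ncol(x))
  keep[qrd$pivot[seq_len(qrd$rank)]] <- TRUE
  structure(
    list(x = x, targets = targets, keep = keep, dropped = cols[!keep]),
    class = "indicator_matrix"
  )
}

#' Calibrate weights by the bounded generalised-regression (GREG) estimator
#'
#' Finds weights `w` minimising the chi-square distance
#' `sum(d * (w/d - 1)^2)` to the initial weights `d` subject to the
#' calibration equations `t(X) %*% w = targets`. The unbounded solution is the
#' closed form `w = d * (1 + X %*% lambda)` with `lambda` solving
#' `t(X) %*% diag(d) %*% X %*% lambda = targets - t(X) %*% d`. With bounds,
#' weights are truncated to `[L*d, U*d]` and the free units re-solved
#' (truncated linear calibration, the GREGWT family) until every weight is in
#' bounds and all residuals meet the tolerance, or `max_iterations` is
#' reached.
#'
#' In household-integrated mode all members of a household share one weight:
#' indicator rows are aggregated over household members and the solve runs at
#' household level, so person-level benchmarks are still honoured.
#'
#' @param initial_weights Positive initial weights `d`, one per person.
#' @param indicator An `indicator_matrix` from [build_indicator_matrix()], or
#'   a plain numeric matrix (then `targets` must be supplied and all columns
#'   are used).
#' @param targets Named target totals; defaults to the indicator's own.
#' @param bounds Length-2 multipliers `c(L, U)` with `L < 1 < U`: weights stay
#'   in `[L*d, U*d]`. `NULL` for the unbounded closed form.
#' @param tolerance Maximum absolute relative error allowed on any target.
#' @param max_iterations Truncation iterations before giving up.
#' @param household_id Optional household ids (one per person); when supplied,
#'   calibration is household-integrated. Initial weights must then be equal
#'   within each household.
#' @return A `calibration_result`: `weights`, `g` (weight ratios `w/d`),
#'   `iterations`, `converged`, `benchmark_residuals` (tibble over all
#'   targets, including redundant ones), `bound_hits`, `dropped_columns`.
#' @export
greg_calibrate <- function(initial_weights, indicator, targets = NULL,
                           bounds = c(0.1, 10), tolerance = 1e-6,
                           max_iterations = 50L, household_id = NULL) {
  if (inherits(indicator, "indicator_matrix")) {
    x_all <- indicator$x
    targets <- targets %||% indicator$targets
    keep <- indicator$keep
    dropped <- indicator$dropped
  } else {
    x_all <- as.matrix(indicator)
    if (is.null(targets)) abort("Supply `targets` with a plain matrix.")
    keep <- rep(TRUE, ncol(x_all))
    dropped <- character()
  }
  d <- initial_weights
  stopifnot(length(d) == nrow(x_all), all(d > 0), all(targets >= 0))
  if (is.null(names(targets))) {
    names(targets) <- colnames(x_all) %||% paste0("target_", seq_along(targets))
  }
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, bounds[1] < 1, bounds[2] > 1, bounds[1] > 0)
  }

  # household integration: aggregate constraints over members, one weight per
  # household
  if (!is.null(household_id)) {
    stopifnot(length(household_id) == length(d))
    first <- !duplicated(household_id)
    dh <- d[first]
    spread <- tapply(d, household_id, function(v) diff(range(v)))
    if (any(spread > 1e-8 * max(d))) {
      abort("Household-integrated calibration needs equal initial weights within each household.")
    }
    xh <- rowsum(x_all, group = household_id, reorder = TRUE)
    hh_order <- sort(unique(household_id))
    fit <- greg_solve(dh[match(hh_order, household_id[first])], xh, targets,
                      keep, bounds, tolerance, max_iterations)
    g_person <- fit$g[match(household_id, hh_order)]
    w_person <- d * g_person
  } else {
    fit <- greg_solve(d, x_all, targets, keep, bounds, tolerance, max_iterations)
    g_person <- fit$g
    w_person <- d * g_person
  }

  achieved <- as.vector(crossprod(x_all, w_person))
  rel <- (achieved - targets) / ifelse(targets == 0, 1, targets)
  residuals <- tibble(
    target = names(targets),
    dimension = sub(":.*$", "", names(targets)),
    category = sub("^[^:]*:", "", names(targets)),
    benchmark = unname(targets),
    achieved = achieved,
    rel_error = unname(rel)
  )
  structure(
    list(
      weights = w_person,
      g = g_person,
      iterations = fit$iterations,
      converged = fit$converged && max(abs(rel)) <= tolerance,
      benchmark_residuals = residuals,
      bound_hits = fit$bound_hits,
      dropped_columns = dropped,
      tolerance = tolerance
    ),
    class = "calibration_result"
  )
}

# internal: truncated chi-square calibration at unit level
greg_solve <- function(d, x_all, targets, keep, bounds, tolerance,
                       max_iterations) {
  x <- x_all[, keep, drop = FALSE]
  tk <- targets[keep]
  n <- length(d)
  w <- d
  fixed <- rep(FALSE, n)
  iterations <- 0L
  converged <- FALSE
  repeat {
    resid <- tk - as.vector(crossprod(x, w))
    relerr <- abs(resid) / ifelse(tk == 0, 1, tk)
    if (max(relerr) <= tolerance) { converged <- TRUE; break }
    if (iterations >= max_iterations) break
    iterations <- iterations + 1L
    free <- !fixed
    if (!any(free)) break
    xf <- x[free, , drop = FALSE]
    a <- crossprod(xf, d[free] * xf)
    lambda <- tryCatch(solve(a, resid), error = function(e) NULL)
    if (is.null(lambda)) {
      if (any(fixed)) break # bound truncation exhausted the free units
      abort("Singular calibration system; prune redundant or conflicting benchmarks.")
    }
    w[free] <- w[free] + d[free] * as.vector(xf %*% lambda)
    if (!is.null(bounds)) {
      lo <- w < bounds[1] * d
      hi <- w > bounds[2] * d
      w[lo] <- bounds[1] * d[lo]
      w[hi] <- bounds[2] * d[hi]
      fixed <- fixed | lo | hi
    }
  }
  list(g = w / d, iterations = iterations, converged = converged,
       bound_hits = sum(fixed))
}

#' Calibrate a person file to a benchmark table
#'
#' Convenience wrapper around [reconcile_benchmark()],
#' [build_indicator_matrix()] and [greg_calibrate()]: the standard
#' static-ageing step. Household-integrated by default because household
#' structures are held fixed while the population is aged.
#'
#' @param persons Person tibble (needs the five benchmark dimensions,
#'   `weight`, and `household_id` when `household_integrated`).
#' @param benchmark Benchmark table for the target year.
#' @param household_integrated Share one weight per household (default TRUE).
#' @inheritParams greg_calibrate
#' @return A list: `persons` (tibble with recalibrated `weight`) and `result`
#'   (the `calibration_result`).
#' @export
calibrate_to_benchmark <- function(persons, benchmark,
                                   household_integrated = TRUE,
                                   bounds = c(0.1, 10), tolerance = 1e-6,
                                   max_iterations = 50L) {
  bm <- reconcile_benchmark(benchmark)
  ind <- build_indicator_matrix(persons, bm)
  res <- greg_calibrate(
    persons$weight, ind,
    bounds = bounds, tolerance = tolerance, max_iterations = max_iterations,
    household_id = if (household_integrated) persons$household_id else NULL
  )
  list(persons = mutate(persons, weight = res$weights), result = res)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  converged:  ", x$converged, " (", x$iterations, " iterations)\n", sep = "")
  cat("  max |rel. error|: ", format(max(abs(x$benchmark_residuals$rel_error))), "\n")
  cat("  weights at a bound: ", x$bound_hits, "\n")
  if (length(x$dropped_columns)) {
    cat("  redundant targets dropped: ", length(x$dropped_columns), "\n")
  }
  invisible(x)
}

#' Tidy per-target diagnostics of a calibration
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return Tibble with one row per benchmark target: `dimension`, `category`,
#'   `benchmark`, `achieved`, `rel_error`.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$benchmark_residuals

#' One-row summary of a calibration
#'
#' @inheritParams tidy.calibration_result
#' @return Tibble with `converged`, `iterations`, `max_abs_rel_error`,
#'   `bound_hits`, `n_targets`, `n_dropped`.
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble(
    converged = x$converged,
    iterations = x$iterations,
    max_abs_rel_error = max(abs(x$benchmark_residuals$rel_error)),
    bound_hits = x$bound_hits,
    n_targets = nrow(x$benchmark_residuals),
    n_dropped = length(x$dropped_columns)
  )
}

#' Plot calibration residuals by benchmark target
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot: relative error per benchmark category.
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  df <- object$benchmark_residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$rel_error)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ dimension, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$tolerance,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "relative error vs benchmark") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
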