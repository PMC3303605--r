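test_that("assembling the insured population adds provincial and senior clones", {
  municipal <- make_insured(sample(25:80, 500, replace = TRUE))
  out <- assemble_insured_population(municipal, provincial_count = 120,
                                     senior_count = 15, seed = 1)
  expect_equal(nrow(out), 635)
  expect_equal(sum(out$stratum == "provincial"), 120)
  expect_true(all(out$age[out$stratum == "senior"] > 68))
  expect_equal(dplyr::n_distinct(out$record_id), 635)
  # identity when nothing is requested
  out0 <- assemble_insured_population(municipal, 0, 0)
  expect_equal(nrow(out0), 500)
  expect_true(all(out0$stratum == "municipal"))
  young <- make_insured(c(30, 40))
  expect_error(assemble_insured_population(young, 0, 5), "older than 68")
})

test_that("stratum sample sizes follow the average-weight rule", {
  expect_equal(stratum_sample_size(4403, 12.542439139), 351)
  expect_equal(stratum_sample_size(0, 12.5), 0)
  # independent oracle: plain division and rounding
  expect_equal(stratum_sample_size(355949, 12.542439139),
               as.integer(round(355949 / 12.542439139)))
  expect_error(stratum_sample_size(10, 0), "positive")
})

test_that("cell tabulation spans the full 72-cell key space", {
  cell <- tabulate_cells(make_insured(integer(0)))
  expect_equal(nrow(cell), 72)
  expect_true(all(cell$n == 0))
  grid <- dplyr::distinct(cell, sex, age_group, employment_status, marital_status)
  expect_equal(nrow(grid), 2 * 6 * 2 * 3)
  # under-15 records are excluded and counted
  expect_message(
    out <- tabulate_cells(make_persons(c(10, 30, 40))),
    "under age 15"
  )
  expect_equal(sum(out$n), 2)
  expect_equal(attr(out, "excluded"), 1)
})

test_that("a generator that forbids young retirees leaves those cells empty", {
  cfg <- synthetic_config(n_households = 800, seed = 12)
  p <- generate_census_sample(cfg)$persons
  ins <- generate_insured_file(cfg, p)
  cells <- tabulate_cells(ins)
  young_retiree <- cells$n[cells$employment_status == "retiree" &
                             cells$age_group %in% c("15-24", "25-34", "35-44")]
  expect_true(all(young_retiree == 0))
})

test_that("deficit resolution preserves totals and moves surplus to adjacent cells", {
  census <- tabulate_cells(make_persons(c(rep(30, 5), rep(42, 4))))
  insured <- tabulate_cells(make_insured(c(rep(31, 3), rep(40, 6))))
  # the 35-44 cell is short by 2; slack exists in the adjacent 25-34 cell
  quotas <- resolve_deficits(census, insured)
  expect_equal(sum(quotas$quota), 9)
  q <- function(g) quotas$quota[quotas$age_group == g &
                                  quotas$sex == "male" &
                                  quotas$employment_status == "employee" &
                                  quotas$marital_status == "married"]
  expect_equal(q("35-44"), 4)
  expect_equal(q("25-34"), 5)
  moves <- attr(quotas, "moves")
  expect_equal(sum(moves$moved), 2)
  expect_match(moves$to[1], "25-34")
  # no deficits: quotas equal demand
  quotas2 <- resolve_deficits(census, tabulate_cells(make_insured(c(30, 41))))
  expect_equal(sum(quotas2$quota), 2)
  expect_equal(nrow(attr(quotas2, "moves")), 0)
  # global infeasibility errors
  expect_error(
    resolve_deficits(tabulate_cells(make_persons(30)),
                     tabulate_cells(make_insured(c(30, 31)))),
    "infeasible"
  )
})

test_that("deficit totals are conserved across randomized instances", {
  set.seed(7)
  for (i in 1:10) {
    census <- tabulate_cells(make_persons(sample(20:80, 60, replace = TRUE),
                                          sex = sample(c("male", "female"), 60, TRUE),
                                          marital_status = sample(pop_levels$marital_status, 60, TRUE)))
    insured <- tabulate_cells(make_insured(sample(20:80, 30, replace = TRUE),
                                           sex = sample(c("male", "female"), 30, TRUE),
                                           marital_status = sample(pop_levels$marital_status, 30, TRUE)))
    quotas <- resolve_deficits(census, insured)
    expect_equal(sum(quotas$quota), 30)
    joined <- dplyr::left_join(quotas, dplyr::rename(census, census_n = n),
                               by = c("sex", "age_group", "employment_status",
                                      "marital_status"))
    expect_true(all(joined$quota <= joined$census_n))
  }
})

test_that("rank pairing matches identical lists perfectly and beats crossed pairings", {
  ins <- make_insured(c(30, 40))
  cen <- make_persons(c(39, 31))
  m <- match_within_cells(ins, cen)
  expect_equal(sort(m$age_gap), c(1, 1))
  expect_equal(sum(m$age_gap), 2) # the crossed pairing would cost 9 + 9 = 18
  expect_equal(m$census_age[m$insured_age == 30], 31)
  same <- match_within_cells(make_insured(c(20, 35, 50)),
                             make_persons(c(50, 20, 35)))
  expect_true(all(same$age_gap == 0))
  g <- glance(m)
  expect_equal(g$n_pairs, 2)
  expect_equal(g$mean_age_gap, 1)
  expect_equal(g$share_gap_lt4, 1)
})

test_that("matched pairs agree on the full cell key and counts are conserved", {
  set.seed(11)
  ages <- sample(20:80, 40, replace = TRUE)
  ins <- make_insured(ages,
                      sex = sample(c("male", "female"), 40, TRUE),
                      marital_status = sample(pop_levels$marital_status, 40, TRUE))
  cen <- make_persons(ages + sample(-3:3, 40, TRUE),
                      sex = ins$sex, marital_status = ins$marital_status)
  cen$age <- pmax(cen$age, 15L)
  # force identical cell counts by construction except for age-group drift:
  # regenerate census ages within the same age group as the insured record
  shift <- ifelse(age_group6(cen$age) == age_group6(ins$age), 0L,
                  ins$age - cen$age)
  cen$age <- cen$age + shift
  m <- match_within_cells(ins, cen)
  expect_equal(nrow(m), 40)
  cenk <- cen[match(m$person_id, cen$person_id), ]
  insk <- ins[match(m$record_id, ins$record_id), ]
  expect_identical(cenk$sex, insk$sex)
  expect_identical(age_group6(cenk$age), age_group6(insk$age))
  expect_identical(cenk$marital_status, insk$marital_status)
  expect_true(all(m$age_gap >= 0))
  # count mismatch errors and names the cell
  expect_error(match_within_cells(make_insured(c(30, 31)), make_persons(30)),
               "counts must be equal")
})

test_that("rank pairing attains the optimal-assignment minimum on small cells", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(2:8, 1)
    a <- sample(25:34, n, replace = TRUE) # one cell group
    b <- sample(25:34, n, replace = TRUE)
    m <- match_within_cells(make_insured(a), make_persons(b))
    expect_equal(sum(m$age_gap), best_pairing_total(a, b))
  }
})

test_that("the multi-variable distance reduces to |age difference| for one variable", {
  spec <- distance_spec()
  spec$variances <- 4
  expect_equal(matching_distance(c(30, 40), c(32, 40), spec), c(1, 0))
  spec2 <- distance_spec(variables = c("age", "income"),
                         importance = c(1, 2), variances = c(1, 100))
  d <- matching_distance(matrix(c(30, 1000), 1), matrix(c(32, 900), 1), spec2)
  expect_equal(d, (30 - 32)^2 / 1 + 2 * (1000 - 900)^2 / 100)
})

test_that("weight adjustment hits its target exactly and scales linearly", {
  seniors <- make_persons(rep(75, 5), employment_status = "retiree",
                          weight = 1150)
  adjusted <- adjust_weights(seniors, 3935)
  expect_equal(sum(adjusted$weight), 3935, tolerance = 1e-9)
  expect_equal(attr(adjusted, "coefficient"), 3935 / 5750, tolerance = 1e-9)
  same <- adjust_weights(seniors, sum(seniors$weight))
  expect_equal(same$weight, seniors$weight)
  double <- adjust_weights(seniors, 2 * sum(seniors$weight))
  expect_equal(double$weight, 2 * seniors$weight)
  expect_error(adjust_weights(make_persons(30, weight = 0), 10), "positive")
})
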