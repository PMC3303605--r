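test_that("earner-group rules partition the population", {
  # household H1: allowance recipient + employee -> employee is low income
  p <- dplyr::bind_rows(
    make_persons(c(40, 60), household_id = c("H1", "H1"),
                 employment_status = c("employee", "nonworking"),
                 living_resource = c(NA, "basic living allowance")),
    make_persons(35, household_id = "H2", employment_status = "employee"),
    make_persons(30, household_id = "H3", employment_status = "nonworking",
                 living_resource = "family support"),
    make_persons(55, household_id = "H4", employment_status = "nonworking",
                 living_resource = "property income"),
    make_persons(8, household_id = "H5", employment_status = "child")
  )
  p$person_id <- sprintf("P%02d", seq_len(nrow(p)))
  out <- classify_earner_groups(p)
  g <- setNames(out$earner_group, out$person_id)
  expect_equal(unname(g[1]), "low")        # employee in allowance family
  expect_equal(unname(g[2]), "other")      # the allowance recipient
  expect_equal(unname(g[3]), "general")    # employee, no allowance in family
  expect_equal(unname(g[4]), "none")       # supported by family members
  expect_equal(unname(g[5]), "other")      # property income
  expect_equal(unname(g[6]), "none")       # child
  expect_true(all(out$earner_group %in% pop_levels$earner_group))
  expect_equal(length(out$earner_group), nrow(p))
})

test_that("fixed allowance assignment passes the parameter through", {
  p <- classify_earner_groups(
    make_persons(c(50, 52, 54), employment_status = "nonworking",
                 living_resource = "basic living allowance")
  )
  a210 <- assign_fixed_incomes(p)
  expect_equal(a210$monthly_income, rep(210, 3))
  a300 <- assign_fixed_incomes(p, allowance = 300)
  expect_equal(a300$monthly_income, rep(300, 3))
  none <- assign_fixed_incomes(classify_earner_groups(make_persons(30)))
  expect_equal(nrow(none), 0)
  expect_error(assign_fixed_incomes(p, allowance = -1), "positive")
})

test_that("donor split honours per-cell ratios and partitions the file", {
  ins <- make_insured(rep(30, 100))
  ratios <- tibble::tibble(sex = "male", age_group = "25-34",
                           employment_status = "employee", ratio = 0.06)
  pools <- split_insured_donors(ins, ratios, seed = 3)
  expect_equal(nrow(pools$low), 6)
  expect_equal(nrow(pools$low) + nrow(pools$general), 100)
  expect_equal(length(intersect(pools$low$record_id, pools$general$record_id)), 0)
  # ratio zero -> empty low pool
  pools0 <- split_insured_donors(ins, dplyr::mutate(ratios, ratio = 0), seed = 3)
  expect_equal(nrow(pools0$low), 0)
  expect_error(split_insured_donors(ins, dplyr::mutate(ratios, ratio = 1.5)),
               "\\[0, 1\\]")
  # partition invariant across random instances
  set.seed(5)
  for (i in 1:5) {
    ins2 <- make_insured(sample(20:80, 50, TRUE),
                         sex = sample(c("male", "female"), 50, TRUE))
    r2 <- low_income_cell_ratios(
      dplyr::mutate(make_persons(sample(20:80, 80, TRUE)),
                    earner_group = sample(c("low", "general"), 80, TRUE))
    )
    pools2 <- split_insured_donors(ins2, r2, seed = i)
    expect_equal(nrow(pools2$low) + nrow(pools2$general), 50)
  }
})

test_that("donor imputation copies incomes within strata and is pure", {
  donor <- make_insured(30, monthly_income = 1000)
  rec <- dplyr::mutate(make_persons(32), earner_group = "general")
  out <- impute_donor_incomes(rec, donor, seed = 1)
  expect_equal(out$monthly_income, 1000)
  expect_equal(out$source, "donor")
  # bijection case: with equal counts each donor is used exactly once
  donors <- make_insured(c(30, 31, 33), monthly_income = c(100, 200, 300))
  recs <- dplyr::mutate(make_persons(c(25, 28, 34)), earner_group = "general")
  out2 <- impute_donor_incomes(recs, donors, seed = 2)
  expect_setequal(out2$monthly_income, c(100, 200, 300))
  # donor pool unmodified (pure function)
  before <- donors
  invisible(impute_donor_incomes(recs, donors, seed = 3))
  expect_identical(donors, before)
  # empty stratum falls back to the nearest age group with a message
  old_donor <- make_insured(70, monthly_income = 555)
  expect_message(
    out3 <- impute_donor_incomes(rec, old_donor, seed = 4),
    "Empty donor stratum"
  )
  expect_equal(out3$monthly_income, 555)
  expect_error(impute_donor_incomes(rec, donor[0, ], seed = 1), "empty")
})

test_that("imputed stratum means converge to donor stratum means", {
  set.seed(9)
  mus <- c(`25-34` = 6.5, `45-54` = 7.2)
  donors <- dplyr::bind_rows(lapply(names(mus), function(g) {
    age <- if (g == "25-34") 28 else 50
    make_insured(rep(age, 400), monthly_income = rlnorm(400, mus[[g]], 0.4))
  }))
  recs <- dplyr::mutate(
    make_persons(c(rep(30, 300), rep(48, 300))), earner_group = "general",
    person_id = sprintf("R%04d", 1:600)
  )
  out <- impute_donor_incomes(recs, donors, seed = 10)
  got <- tapply(out$monthly_income, age_group6(recs$age), mean)
  want <- tapply(donors$monthly_income, age_group6(donors$age), mean)
  # Monte-Carlo error: donor sd / sqrt(n) ~ a few per cent of the mean
  expect_equal(unname(got), unname(want), tolerance = 0.1)
})

test_that("family income quintiles hit the textbook cases", {
  fam <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(make_persons(40, household_id = paste0("F", i)),
                  monthly_income = 10 * i, person_id = paste0("Q", i))
  }))
  s <- family_income_quintiles(fam)
  expect_equal(s$mean_income, 12 * c(10, 20, 30, 40, 50))
  expect_equal(attr(s, "top_bottom_ratio"), 5)
  expect_equal(s$weight_share, rep(0.2, 5))
  flat <- dplyr::mutate(fam, monthly_income = 25)
  expect_equal(attr(family_income_quintiles(flat), "top_bottom_ratio"), 1)
  expect_error(family_income_quintiles(fam[0, ]), "empty")
})

test_that("quintile weights stay within one family of 20% and the ratio grows with dispersion", {
  set.seed(31)
  build <- function(sdlog) {
    n <- 400
    dplyr::mutate(
      make_persons(rep(40, n), household_id = sprintf("F%03d", 1:n),
                   weight = runif(n, 1, 3)),
      monthly_income = rlnorm(n, 7, sdlog),
      person_id = sprintf("Q%03d", 1:n)
    )
  }
  lo <- family_income_quintiles(build(0.3))
  hi <- family_income_quintiles(build(0.9))
  expect_gt(attr(hi, "top_bottom_ratio"), attr(lo, "top_bottom_ratio"))
  fams <- attr(hi, "families")
  max_w <- max(fams$weight) / sum(fams$weight)
  expect_true(all(abs(hi$weight_share - 0.2) <= max_w + 1e-12))
})

test_that("mean disposable income is a weighted annualised mean", {
  one <- dplyr::mutate(make_persons(40), monthly_income = 1000)
  expect_equal(mean_disposable_income(one), 12000)
  two <- dplyr::mutate(make_persons(c(40, 50), weight = c(3, 1)),
                       monthly_income = c(1000, 2000))
  expect_equal(mean_disposable_income(two), (3 * 12000 + 24000) / 4)
  expect_equal(mean_disposable_income(dplyr::mutate(two, monthly_income = 2 * monthly_income)),
               2 * mean_disposable_income(two))
})

test_that("end-to-end imputation assigns every person exactly one income", {
  cfg <- synthetic_config(n_households = 400, seed = 14)
  p <- generate_census_sample(cfg)$persons
  ins <- generate_insured_file(cfg, p)
  p <- classify_earner_groups(p)
  pools <- split_insured_donors(ins, low_income_cell_ratios(p), seed = 15)
  out <- suppressMessages(impute_all_incomes(p, pools, seed = 16))
  expect_equal(nrow(out), nrow(p))
  expect_true(all(out$monthly_income >= 0))
  expect_true(all(out$monthly_income[out$earner_group == "none"] == 0))
  expect_true(all(out$monthly_income[out$earner_group == "other"] == 210))
  expect_true(all(out$monthly_income[out$earner_group %in% c("low", "general")] > 0))
})
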