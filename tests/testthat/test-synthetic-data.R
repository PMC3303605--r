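test_that("benchmark fixture returns the published totals and is internally consistent", {
  b05 <- benchmark_fixture(2005)
  expect_equal(b05$total[b05$dimension == "total"], 6085700)
  b00 <- benchmark_fixture(2000)
  expect_equal(b00$total[b00$category == "urban"], 3046230)
  expect_equal(b00$total[b00$category == "rural"], 2726420)
  expect_equal(3046230 + 2726420, 5772650)
  for (y in c(2000, 2005, 2010)) {
    b <- benchmark_fixture(y)
    grand <- b$total[b$dimension == "total"]
    sums <- tapply(b$total[b$dimension != "total"], b$dimension[b$dimension != "total"], sum)
    # categories are printed to the nearest ten, so dimensions may miss the
    # grand total by a few tens
    expect_true(all(abs(sums - grand) <= 40), label = paste("year", y))
  }
  expect_error(benchmark_fixture(2008), "build_benchmarks")
})

test_that("reconciliation makes every dimension sum exactly to the grand total", {
  b <- reconcile_benchmark(benchmark_fixture(2000))
  grand <- b$total[b$dimension == "total"]
  sums <- tapply(b$total[b$dimension != "total"], b$dimension[b$dimension != "total"], sum)
  expect_equal(as.numeric(sums), rep(grand, length(sums)))
  expect_s3_class(attr(b, "adjustments"), "tbl_df")
})

test_that("config validation rejects malformed probability vectors", {
  expect_error(synthetic_config(household_size_probs = rep(0.2, 8)), "sum to 1")
  expect_error(synthetic_config(insured_fraction = 1.5), "insured_fraction")
  expect_error(
    synthetic_config(living_resource_shares = c(
      "family support" = 0.5, pension = 0.2, "basic living allowance" = 0.1,
      "property income" = 0.1, other = 0.2
    )),
    "sum to 1"
  )
})

test_that("zero households yields empty, well-typed output", {
  s <- generate_census_sample(synthetic_config(n_households = 0, seed = 1))
  expect_equal(nrow(s$persons), 0)
  expect_equal(nrow(s$households), 0)
  expect_true(all(c("person_id", "household_id", "sex", "age", "weight") %in%
                    names(s$persons)))
})

test_that("generated persons satisfy the record invariants", {
  s <- generate_census_sample(synthetic_config(n_households = 300, seed = 11))
  p <- s$persons
  expect_true(all(p$weight > 0))
  expect_true(all(p$education[p$age < 6] == "under 6"))
  expect_true(all(p$education[p$age >= 6] != "under 6"))
  expect_true(all(p$employment_status[p$age < 15] == "child"))
  expect_true(all(p$employment_status[p$age >= 15] != "child"))
  # every person belongs to exactly one existing household
  expect_true(all(p$household_id %in% s$households$household_id))
  expect_equal(nrow(p), sum(s$households$size))
  sizes <- dplyr::count(p, household_id)
  expect_equal(sort(sizes$n), sort(s$households$size))
  # each household has an adult
  max_age <- tapply(p$age, p$household_id, max)
  expect_true(all(max_age >= 18))
  # nonworking adults all carry a living resource
  nw <- p[p$employment_status == "nonworking" & p$age >= 15, ]
  expect_true(all(!is.na(nw$living_resource)))
})

test_that("default household sizes reproduce the study's sample scale", {
  # 1,761 households averaging ~3.06 persons gives ~5,395 individuals
  s <- generate_census_sample(synthetic_config(n_households = 1761, seed = 2))
  expect_equal(nrow(s$persons) / 1761, 5395 / 1761, tolerance = 0.05)
})

test_that("generation is bit-identical under one seed and differs across seeds", {
  cfg <- synthetic_config(n_households = 120, seed = 99)
  expect_identical(generate_census_sample(cfg), generate_census_sample(cfg))
  cfg2 <- synthetic_config(n_households = 120, seed = 100)
  expect_false(identical(generate_census_sample(cfg)$persons$age,
                         generate_census_sample(cfg2)$persons$age))
  ins1 <- generate_insured_file(cfg, generate_census_sample(cfg)$persons)
  ins2 <- generate_insured_file(cfg, generate_census_sample(cfg)$persons)
  expect_identical(ins1, ins2)
})

test_that("marginal shares converge to the configured targets", {
  cfg <- synthetic_config(n_households = 5000, seed = 3)
  p <- generate_census_sample(cfg)$persons
  shares <- benchmark_shares(cfg$marginal_targets)
  observed <- list(
    sex = p$sex,
    age_group = age_group8(p$age),
    residential_status = p$residential_status,
    nationality = p$nationality,
    education = p$education
  )
  for (d in names(observed)) {
    tab <- 100 * table(observed[[d]]) / nrow(p)
    tgt <- shares[shares$dimension == d, ]
    for (k in tgt$category) {
      got <- if (k %in% names(tab)) tab[[k]] else 0
      expect_lt(abs(got - tgt$share[tgt$category == k]), 2)
    }
  }
})

test_that("insured file respects eligibility, strata and determinism", {
  cfg <- synthetic_config(n_households = 1500, seed = 5)
  p <- generate_census_sample(cfg)$persons
  ins <- generate_insured_file(cfg, p)
  # drawn only from employees/retirees; the cell-key combination of every
  # insured record exists in the census file
  src <- p[match(ins$person_id, p$person_id), ]
  expect_true(all(src$employment_status %in% c("employee", "retiree")))
  expect_identical(ins$age, src$age)
  expect_identical(ins$marital_status, src$marital_status)
  # senior stratum only above age 68
  expect_true(all(ins$age[ins$stratum == "senior"] > 68))
  # realized stratum proportions within binomial sampling error (4 sd)
  n <- nrow(ins)
  for (s in c("municipal", "provincial")) {
    pr <- cfg$stratum_probs[[s]]
    expect_lt(abs(mean(ins$stratum == s) - pr), 4 * sqrt(pr * (1 - pr) / n) + 0.01)
  }
  expect_true(all(ins$monthly_income >= 0))
})

test_that("insured fraction zero gives an empty file; no eligible donors warn", {
  cfg0 <- synthetic_config(n_households = 50, insured_fraction = 0, seed = 8)
  p <- generate_census_sample(cfg0)$persons
  expect_equal(nrow(generate_insured_file(cfg0, p)), 0)
  kids <- make_persons(c(3, 7), employment_status = "child")
  expect_warning(out <- generate_insured_file(cfg0, kids), "empty insured file")
  expect_equal(nrow(out), 0)
  expect_error(generate_insured_file(cfg0, p[0, ]), "nonempty")
})

test_that("shifting the income location by log(2) doubles incomes under a common seed", {
  cfg <- synthetic_config(n_households = 400, seed = 21)
  p <- generate_census_sample(cfg)$persons
  im2 <- cfg$income_model
  im2$meanlog <- im2$meanlog + log(2)
  cfg2 <- synthetic_config(n_households = 400, income_model = im2, seed = 21)
  inc1 <- generate_insured_file(cfg, p)$monthly_income
  inc2 <- generate_insured_file(cfg2, p)$monthly_income
  expect_equal(mean(inc2) / mean(inc1), 2, tolerance = 1e-3)
})
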