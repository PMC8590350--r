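p0 <- cost_params()

test_that("human-capital death loss matches hand-derived anchor cases", {
  # one remaining working year, undiscounted
  expect_equal(hc_death_loss(64, "unknown", p0), 0.75 * 46268)
  expect_equal(hc_death_loss(70, "male", p0), 0)
  # age 52 female: 13-year discounted annuity
  expect_equal(hc_death_loss(52, "female", p0),
               0.75 * 37847 * sum(1.015^-(0:12)))
  # unknown age: working fraction times the assumed-age loss
  expect_equal(hc_death_loss(NA, "male", p0),
               0.47 * hc_death_loss(52, "male", p0))
  expect_error(hc_death_loss(-5, "male", p0),
               class = "adrburden_domain_error")
})

test_that("closed-form annuity equals the year-by-year loop for every age, sex, rate", {
  for (r in c(0, 0.015, 0.03)) {
    p <- cost_params(discount_rate = r)
    for (s in c("female", "male", "unknown")) {
      expected <- vapply(c(0:90, NA), hc_loop_oracle, numeric(1),
                         sex = s, p = p)
      got <- hc_death_loss(c(0:90, NA), rep(s, 92), p)
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})

test_that("death loss is monotone in age over the working range and in the rate", {
  losses <- hc_death_loss(19:64, rep("unknown", 46), p0)
  expect_true(all(diff(losses) <= 0))
  p_hi <- cost_params(discount_rate = 0.03)
  p_lo <- cost_params(discount_rate = 0)
  expect_true(all(hc_death_loss(19:64, rep("unknown", 46), p_hi) <=
                    hc_death_loss(19:64, rep("unknown", 46), p0)))
  # zero discount equals the plain sum of remaining working years
  expect_equal(hc_death_loss(30, "male", p_lo), 0.75 * 54690 * 35)
})

test_that("disability loss composes the decrements and honors the benefit offset", {
  p_zero <- cost_params(disability_employment_loss = 0,
                        disability_income_loss = 0)
  expect_equal(hc_disability_loss(40, "female", p_zero), 0)
  # single remaining working year: annual loss times the composed fraction
  expect_equal(hc_disability_loss(64, "unknown", p0),
               0.75 * 46268 * (1 - 0.775 * 0.685))
  expect_equal(hc_disability_loss(NA, "female", p0),
               0.47 * hc_disability_loss(52, "female", p0))
  p_add <- cost_params(disability_decrement = "additive")
  expect_equal(hc_disability_loss(64, "unknown", p_add),
               0.75 * 46268 * (0.225 + 0.315))
  p_ben <- cost_params(apply_disability_benefit = TRUE)
  expect_equal(hc_disability_loss(64, "unknown", p_ben),
               0.75 * 46268 * (1 - 0.775 * 0.685) - 11506)
  p_ben_floor <- cost_params(apply_disability_benefit = TRUE,
                             disability_income_loss = 0.001,
                             disability_employment_loss = 0,
                             income = c(female = 100, male = 100,
                                        unknown = 100))
  expect_equal(hc_disability_loss(64, "unknown", p_ben_floor), 0)
})

test_that("hospitalization and OMIC opportunity costs follow the daily wage", {
  expect_equal(hosp_opportunity_cost(NA, "unknown", p0),
               2.3 * (46268 / 365) * 0.75)
  expect_equal(hosp_opportunity_cost(30, "male", p0, los = 0), 0)
  # strictly increasing in length of stay
  expect_gt(hosp_opportunity_cost(30, "male", p0, los = 4),
            hosp_opportunity_cost(30, "male", p0, los = 2))
  expect_equal(omic_opportunity_cost("unknown", p0), (46268 / 365) * 0.75)
  expect_gt(omic_opportunity_cost("male", p0),
            omic_opportunity_cost("female", p0))
  p_noemp <- cost_params(employment_rate = 0)
  expect_equal(omic_opportunity_cost("female", p_noemp), 0)
})

test_that("direct costs come from the age-band table with the weighted-average fallback", {
  expect_equal(direct_hosp_cost(NA, p0), 4205)
  expect_equal(direct_hosp_cost(10, p0), 1766)
  expect_equal(direct_hosp_cost(85, p0), 5325)
  expect_equal(direct_omic_cost(p0), 417)
  expect_equal(direct_omic_cost(cost_params(omic_unit_cost = 208)), 208)
  bad_bands <- default_hosp_bands()
  bad_bands$cost[1] <- -10
  expect_error(cost_params(hosp_bands = bad_bands),
               class = "adrburden_config_error")
})

test_that("friction losses apply only to working-age deaths and disabilities", {
  expect_equal(friction_loss("hospitalization", 40, "male", p0), 0)
  expect_equal(friction_loss("omic", 40, "male", p0), 0)
  p48 <- cost_params(income = c(female = 48000, male = 48000,
                                unknown = 48000))
  expect_equal(friction_loss("death", 40, "male", p48),
               0.75 * 48000 * 0.25)
  expect_equal(friction_loss("disability", 40, "male", p48),
               0.75 * 48000 * 0.25 * 0.225)
  expect_equal(friction_loss("death", 70, "male", p48), 0)
  expect_equal(friction_loss("death", NA, "male", p48),
               0.47 * 0.75 * 48000 * 0.25)
  expect_equal(friction_loss("death", 40, "male",
                             cost_params(friction_months = 0)), 0)
})

test_that("aggregation sums per-report costs, annualizes and divides by recipients", {
  u <- users_estimate(1000, 2014:2018)
  one_omic <- make_cohort("omic")
  bd <- aggregate_burden(one_omic, u, p0)
  hs <- bd$totals[bd$totals$perspective == "health_system", ]
  expect_equal(hs$total, 417 / 5)
  expect_equal(hs$per_recipient, 417 / 5 / 1000)

  empty <- make_cohort(character(0))
  bd0 <- aggregate_burden(empty, u, p0)
  expect_true(all(bd0$costs$annual_cost == 0))
  expect_true(all(bd0$totals$total == 0))
})

test_that("societal total equals health-system total plus friction losses exactly", {
  g <- generate_cvar(synthetic_config(n_reports = 400, seed = 71))
  cl <- classify_outcomes(join_and_dedup(g$tables))
  u <- users_estimate(5000, 2014:2018)
  bd <- aggregate_burden(cl, u, p0)
  t <- function(persp) bd$totals$total[bd$totals$perspective == persp]
  fr <- sum(friction_loss("death",
                          cl$age_years[cl$primary_category == "death"],
                          cl$sex[cl$primary_category == "death"], p0)) +
    sum(friction_loss("disability",
                      cl$age_years[cl$primary_category == "disability"],
                      cl$sex[cl$primary_category == "disability"], p0))
  expect_equal(t("societal"), t("health_system") + fr / 5)
  # category totals add up to the perspective totals exactly
  sums <- tapply(bd$costs$annual_cost, bd$costs$perspective, sum)
  expect_equal(as.numeric(sums[bd$totals$perspective]), bd$totals$total)
})

test_that("costs scale linearly in income", {
  cl <- make_cohort(c("death", "disability", "hospitalization", "omic"),
                    age = c(40, 50, 60, NA), sex = "female")
  u <- users_estimate(1000, 2014:2018)
  p2 <- cost_params(income = 2 * p0$income)
  bd1 <- aggregate_burden(cl, u, p0)
  bd2 <- aggregate_burden(cl, u, p2)
  pat1 <- bd1$costs$annual_cost[bd1$costs$perspective == "patient"]
  pat2 <- bd2$costs$annual_cost[bd2$costs$perspective == "patient"]
  expect_equal(pat2, 2 * pat1)
  hs1 <- bd1$costs$annual_cost[bd1$costs$perspective == "health_system"]
  hs2 <- bd2$costs$annual_cost[bd2$costs$perspective == "health_system"]
  expect_equal(hs2, hs1) # direct costs do not depend on income
})

test_that("parameter files round-trip through YAML", {
  p <- cost_params(discount_rate = 0.02, omic_unit_cost = 300,
                   unknown_age_working_fraction = 0.45)
  path <- tempfile(fileext = ".yaml")
  write_cost_params(p, path)
  back <- read_cost_params(path)
  expect_equal(back$discount_rate, 0.02)
  expect_equal(back$omic_unit_cost, 300)
  expect_equal(back$income, p$income)
  expect_equal(back$hosp_bands, p$hosp_bands)
  expect_error(read_cost_params(tempfile()),
               class = "adrburden_config_error")
})
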