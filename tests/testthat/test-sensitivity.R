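p0 <- cost_params()
u0 <- users_estimate(5000, 2014:2018)

small_cohort <- function(seed = 83, n = 300) {
  g <- generate_cvar(synthetic_config(
    n_reports = n,
    p_outcome = c(death = 0.15, disability = 0.15, hospitalization = 0.3,
                  omic = 0.4, nonserious = 0.1),
    seed = seed
  ))
  classify_outcomes(join_and_dedup(g$tables))
}

test_that("a degenerate one-way range reproduces the base case at both bounds", {
  cl <- small_cohort()
  spec <- tibble::tibble(parameter = "discount_rate", low = 0.015,
                         high = 0.015)
  ow <- one_way(cl, u0, p0, spec)
  base <- adrburden:::breakdown_cells(aggregate_burden(cl, u0, p0))
  for (b in c("low", "high")) {
    sub <- ow[ow$bound == b, ]
    expect_equal(setNames(sub$annual_cost,
                          paste(sub$perspective, sub$category, sep = ".")),
                 base)
  }
})

test_that("death HC cost decreases in the discount rate across its one-way range", {
  cl <- small_cohort()
  ow <- one_way(cl, u0, p0,
                tibble::tibble(parameter = "discount_rate", low = 0,
                               high = 0.03))
  death <- function(b) {
    ow$annual_cost[ow$bound == b & ow$perspective == "patient" &
                     ow$category == "death"]
  }
  base <- aggregate_burden(cl, u0, p0)
  base_death <- base$costs$annual_cost[base$costs$perspective == "patient" &
                                         base$costs$category == "death"]
  expect_gt(death("low"), base_death)
  expect_lt(death("high"), base_death)
})

test_that("OMIC one-way bounds rescale the direct OMIC cost exactly", {
  cl <- small_cohort()
  ow <- one_way(cl, u0, p0,
                tibble::tibble(parameter = "omic_unit_cost", low = 208,
                               high = 626))
  base <- aggregate_burden(cl, u0, p0)
  base_omic <- base$costs$annual_cost[base$costs$perspective == "health_system" &
                                        base$costs$category == "omic"]
  omic <- function(b) {
    ow$annual_cost[ow$bound == b & ow$perspective == "health_system" &
                     ow$category == "omic"]
  }
  expect_equal(omic("low"), base_omic * 208 / 417)
  expect_equal(omic("high"), base_omic * 626 / 417)
})

test_that("an all-zero-variance PSA collapses exactly onto the base case", {
  cl <- small_cohort()
  spec <- psa_spec(n_iterations = 10, seed = 5, income_cv = 0,
                   hosp_cost_cv = 0, los_cv = 0,
                   disability_income_loss_cv = 0, employment_sd = 0,
                   disability_employment_sd = 0)
  res <- psa(cl, u0, p0, spec)
  base <- adrburden:::breakdown_cells(aggregate_burden(cl, u0, p0))
  expect_equal(res$summary$mean, unname(base))
  expect_equal(res$summary$`p2.5`, res$summary$`p97.5`)
  expect_equal(res$summary$mean, res$summary$`p97.5`)
})

test_that("the PSA is bit-identical under a fixed seed", {
  cl <- small_cohort(n = 120)
  spec <- psa_spec(n_iterations = 50, seed = 99)
  r1 <- psa(cl, u0, p0, spec)
  r2 <- psa(cl, u0, p0, spec)
  expect_identical(r1$summary, r2$summary)
})

test_that("the default-variance PSA mean stays near the base case", {
  cl <- small_cohort(n = 400)
  res <- psa(cl, u0, p0, psa_spec(n_iterations = 1500, seed = 7))
  base <- adrburden:::breakdown_cells(aggregate_burden(cl, u0, p0))
  nonzero <- base > 0
  rel <- abs(res$summary$mean[nonzero] - base[nonzero]) / base[nonzero]
  expect_true(all(rel < 0.02))
  # interval sanity: sorted draws keep p2.5 <= p97.5, base inside for totals
  expect_true(all(res$summary$`p2.5` <= res$summary$`p97.5`))
})

test_that("doubling the income CV weakly widens patient-perspective intervals", {
  cl <- small_cohort(n = 250)
  narrow <- psa(cl, u0, p0, psa_spec(n_iterations = 400, seed = 31))
  wide <- psa(cl, u0, p0, psa_spec(n_iterations = 400, seed = 31,
                                   income_cv = 0.22))
  width <- function(res) {
    s <- res$summary[res$summary$perspective == "patient" &
                       res$summary$category == "total", ]
    s$`p97.5` - s$`p2.5`
  }
  expect_gte(width(wide), width(narrow))
})

test_that("PSA draw means match the analytic expectation on a single report", {
  # one OMIC report: patient cost is linear in the income draw, so the
  # draw mean must converge to employment_rate * E[income] / 365
  cl <- make_cohort("omic", age = 40, sex = "female")
  spec <- psa_spec(n_iterations = 2000, seed = 11, keep_draws = TRUE)
  res <- psa(cl, u0, p0, spec)
  draws <- res$draws[, "patient.omic"]
  analytic <- 0.75 * 37847 / 365 / 5
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - analytic), 3 * se)
  hs <- res$draws[, "health_system.omic"]
  expect_equal(unique(hs), 417 / 5) # OMIC direct cost is not a PSA input
})

test_that("the base case falls inside the 95-percentile interval across generator seeds", {
  failures <- 0
  for (s in 1:20) {
    cl <- small_cohort(seed = 200 + s, n = 150)
    base <- adrburden:::breakdown_cells(aggregate_burden(cl, u0, p0))
    res <- psa(cl, u0, p0, psa_spec(n_iterations = 300, seed = s))
    tot <- res$summary[res$summary$category == "total", ]
    base_tot <- base[paste0(tot$perspective, ".total")]
    inside <- all(base_tot >= tot$`p2.5` & base_tot <= tot$`p97.5`)
    if (!inside) failures <- failures + 1
  }
  expect_lte(failures, 1)
})
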