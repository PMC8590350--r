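test_that("configuration validation rejects invalid probabilities", {
  expect_error(synthetic_config(p_outcome = c(death = 1.2, disability = 0,
                                              hospitalization = 0, omic = 0,
                                              nonserious = 0)),
               class = "adrburden_config_error")
  expect_error(synthetic_config(sex_probs = c(female = 0.5, male = 0.4,
                                              unknown = 0.2)),
               class = "adrburden_config_error")
  expect_error(synthetic_config(n_reports = 0),
               class = "adrburden_config_error")
})

test_that("degenerate outcome probabilities give a serious-free cohort", {
  cfg <- synthetic_config(
    n_reports = 200,
    p_outcome = c(death = 0, disability = 0, hospitalization = 0, omic = 0,
                  nonserious = 1),
    seed = 11
  )
  g <- generate_cvar(cfg)
  expect_equal(unname(g$truth$flag_counts[["serious"]]), 0)
  expect_equal(unname(g$truth$flag_counts[["nonserious"]]), 200)
  expect_true(all(g$tables$outcomes$outcome_label == "Not serious"))
})

test_that("duplicate injection emits the expected row counts", {
  g <- generate_cvar(synthetic_config(n_reports = 100,
                                      duplicate_fraction = 0.5, seed = 3))
  expect_equal(nrow(g$tables$reports), 150)
  expect_equal(length(unique(g$tables$reports$report_id)), 100)
})

test_that("realized death count falls in the binomial 99% interval", {
  cfg <- synthetic_config(
    n_reports = 10000,
    p_outcome = c(death = 0.002, disability = 0.015, hospitalization = 0.27,
                  omic = 0.65, nonserious = 0.03),
    seed = 20
  )
  g <- generate_cvar(cfg)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.002)
  deaths <- unname(g$truth$flag_counts[["death"]])
  expect_gte(deaths, bounds[1])
  expect_lte(deaths, bounds[2])
})

test_that("generation is deterministic under a fixed seed, byte-identically", {
  cfg <- synthetic_config(n_reports = 150, duplicate_fraction = 0.2, seed = 42)
  g1 <- generate_cvar(cfg)
  g2 <- generate_cvar(cfg)
  expect_identical(g1$tables$reports, g2$tables$reports)
  expect_identical(g1$truth$flag_counts, g2$truth$flag_counts)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_extract(g1$tables, d1)
  p2 <- write_extract(g2$tables, d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", 1e7), readBin(p2[[k]], "raw", 1e7))
  }
})

test_that("ground truth can be serialized as YAML", {
  g <- generate_cvar(synthetic_config(n_reports = 30, seed = 5))
  path <- tempfile(fileext = ".yaml")
  write_ground_truth(g$truth, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$n_reports, 30)
  expect_equal(back$flag_counts$death,
               unname(g$truth$flag_counts[["death"]]))
})

test_that("oracle is zero for a cost-free cohort and linear for OMIC-only", {
  params <- cost_params(period_years = 5)
  cfg0 <- synthetic_config(
    n_reports = 100,
    p_outcome = c(death = 0, disability = 0, hospitalization = 0, omic = 0,
                  nonserious = 1))
  orc0 <- expected_burden_oracle(cfg0, params)
  expect_equal(unname(orc0$totals), c(0, 0, 0))

  cfg_omic <- synthetic_config(
    n_reports = 1000,
    p_outcome = c(death = 0, disability = 0, hospitalization = 0, omic = 1,
                  nonserious = 0))
  orc <- expected_burden_oracle(cfg_omic, params)
  expect_equal(unname(orc$costs$health_system[["omic"]]),
               1000 * 417 / 5)
  expect_equal(unname(orc$costs$health_system[["hospitalization"]]), 0)
})

test_that("oracle matches the mean pipeline burden over repeated generation", {
  params <- cost_params(period_years = 5)
  cfg_base <- synthetic_config(
    n_reports = 300,
    p_outcome = c(death = 0.1, disability = 0.1, hospitalization = 0.3,
                  omic = 0.4, nonserious = 0.1),
    age_model = list(ages = 10:80, probs = rep(1 / 71, 71),
                     unknown_fraction = 0.15),
    annual_users = 5000
  )
  orc <- expected_burden_oracle(cfg_base, params)
  n_runs <- 200
  cells <- c("patient", "health_system", "societal")
  runs <- matrix(NA_real_, n_runs, 3, dimnames = list(NULL, cells))
  for (i in seq_len(n_runs)) {
    cfg <- cfg_base
    cfg$seed <- 1000L + i
    bd <- run_burden_on(generate_cvar(cfg), params)
    runs[i, ] <- bd$totals$total[match(cells, bd$totals$perspective)]
  }
  for (cc in cells) {
    se <- sd(runs[, cc]) / sqrt(n_runs)
    expect_lt(abs(mean(runs[, cc]) - orc$totals[[cc]]), 3 * se)
  }
})

test_that("pipeline burden converges to the closed-form oracle at n = 10,000", {
  params <- cost_params(period_years = 5)
  cfg <- balanced_config(n_reports = 10000, seed = 101)
  orc <- expected_burden_oracle(cfg, params)
  bd <- run_burden_on(generate_cvar(cfg), params)
  for (persp in c("patient", "health_system", "societal")) {
    exp_cells <- orc$costs[[persp]]
    got <- bd$costs$annual_cost[bd$costs$perspective == persp]
    names(got) <- bd$costs$category[bd$costs$perspective == persp]
    for (cat in names(exp_cells)) {
      if (exp_cells[[cat]] == 0) {
        expect_equal(got[[cat]], 0)
      } else {
        expect_lt(abs(got[[cat]] - exp_cells[[cat]]) / exp_cells[[cat]], 0.05)
      }
    }
    tot <- bd$totals$total[bd$totals$perspective == persp]
    expect_lt(abs(tot - orc$totals[[persp]]) / orc$totals[[persp]], 0.05)
  }
})
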