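# Independent oracles and small fixture builders used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Year-by-year human-capital loss: an explicit loop over calendar years,
# deliberately naive, against which the closed-form annuity is checked.
hc_loop_oracle <- function(age, sex, p) {
  inc <- p$income[[sex]]
  if (is.na(age)) {
    return(p$unknown_age_working_fraction *
             hc_loop_oracle(p$unknown_age_assumed, sex, p))
  }
  if (age > p$working_age[2]) return(0)
  total <- 0
  for (y in 0:(p$working_age[2] - age)) {
    a <- age + y
    if (a >= p$working_age[1]) {
      total <- total + p$employment_rate * inc / (1 + p$discount_rate)^y
    }
  }
  total
}

# Step-by-step DerSimonian-Laird evaluation with scalar accumulators.
dl_loop_oracle <- function(p, v) {
  k <- length(p)
  sw <- sw2 <- swp <- 0
  for (i in seq_len(k)) {
    w <- 1 / v[i]
    sw <- sw + w
    sw2 <- sw2 + w^2
    swp <- swp + w * p[i]
  }
  p_fe <- swp / sw
  Q <- 0
  for (i in seq_len(k)) Q <- Q + (1 / v[i]) * (p[i] - p_fe)^2
  tau2 <- if (k == 1) 0 else max(0, (Q - (k - 1)) / (sw - sw2 / sw))
  swr <- swrp <- 0
  for (i in seq_len(k)) {
    wr <- 1 / (v[i] + tau2)
    swr <- swr + wr
    swrp <- swrp + wr * p[i]
  }
  list(pooled = swrp / swr, se = sqrt(1 / swr), Q = Q, tau2 = tau2)
}

# Hand-built classified cohort, bypassing the IO layer.
make_cohort <- function(category, age = 40, sex = "unknown",
                        year = 2014:2018) {
  n <- length(category)
  tibble::tibble(
    report_id = sprintf("T%03d", seq_len(n)),
    initial_report_date = as.Date(sprintf("%d-06-15",
                                          rep_len(year, n))),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    flag_death = category == "death",
    flag_disability = category == "disability",
    flag_hospitalization = category == "hospitalization",
    flag_omic = category == "omic",
    primary_category = factor(category,
                              levels = c("death", "disability",
                                         "hospitalization", "omic",
                                         "nonserious"))
  )
}

# Balanced, high-count generator configuration used for oracle-recovery
# checks: each primary category draws roughly a quarter of the cohort and
# ages sit inside the working-age window, so sampling noise per cell stays
# well below the recovery tolerance.
balanced_config <- function(n_reports, seed) {
  synthetic_config(
    n_reports = n_reports,
    years = 2014:2018,
    p_outcome = c(death = 0.25, disability = 1 / 3, hospitalization = 0.5,
                  omic = 0.9, nonserious = 0.025),
    sex_probs = c(female = 0.45, male = 0.45, unknown = 0.10),
    age_model = list(ages = 35:50, probs = rep(1 / 16, 16),
                     unknown_fraction = 0.10),
    annual_users = 20000,
    seed = seed
  )
}

run_burden_on <- function(gen, params) {
  reports <- suppressMessages(join_and_dedup(gen$tables))
  cohort <- suppressMessages(classify_outcomes(reports))
  users <- users_estimate(mean(gen$truth$annual_users), gen$truth$years)
  aggregate_burden(cohort, users, params)
}
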