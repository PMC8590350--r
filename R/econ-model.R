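# Cost-of-illness primitives: human-capital (HC) opportunity costs, direct
# healthcare costs, and friction-cost (FC) productivity losses, all
# vectorized over reports. The optional `income`/`employment_rate`/... args
# let the probabilistic sensitivity analysis substitute per-report or
# per-iteration draws while keeping a single costing code path.

sex_income <- function(sex, params, income = NULL) {
  if (!is.null(income)) return(income)
  i <- match(sex, names(params$income))
  if (anyNA(i)) {
    abort("`sex` must be one of 'female', 'male', 'unknown'.",
          class = "adrburden_domain_error")
  }
  unname(params$income[i])
}

# Present-value factor of one currency unit per working year remaining from
# age `age` (death/onset year = t 0, undiscounted), counting only years with
# age inside `working_age`. Returns 0 past working age; NA ages are the
# caller's responsibility.
working_annuity <- function(age, discount_rate, working_age = c(19, 64)) {
  lo <- working_age[1]
  hi <- working_age[2]
  start <- pmax(age, lo) - age
  end <- hi - age
  out <- numeric(length(age))
  ok <- !is.na(age) & age <= hi
  if (discount_rate == 0) {
    out[ok] <- end[ok] - start[ok] + 1
  } else {
    v <- 1 / (1 + discount_rate)
    out[ok] <- (v^start[ok] - v^(end[ok] + 1)) / (1 - v)
  }
  out
}

check_age <- function(age_years) {
  if (any(!is.na(age_years) & age_years < 0)) {
    abort("Ages must be nonnegative.", class = "adrburden_domain_error")
  }
}

# Unknown-age imputation shared by the HC and FC calculations: an
# unknown-age patient contributes `unknown_age_working_fraction` times the
# value at the assumed age.
impute_unknown <- function(age_years, params) {
  known <- !is.na(age_years)
  list(
    age = ifelse(known, age_years, params$unknown_age_assumed),
    scale = ifelse(known, 1, params$unknown_age_working_fraction)
  )
}

#' Human-capital lifetime wage loss for an ADR-related death
#'
#' Present value of employment-weighted income forgone from the year of
#' death until the end of working age (inclusive). Income accrues only in
#' years where the patient would have been aged within `params$working_age`;
#' for children the stream starts (discounted) at the working-age minimum.
#' The first lost year is undiscounted. Unknown-age patients contribute
#' `unknown_age_working_fraction` times the loss evaluated at
#' `unknown_age_assumed`.
#'
#' @param age_years Numeric vector of ages at death; `NA` means unknown.
#' @param sex Character vector (`"female"`, `"male"`, `"unknown"`).
#' @param params A [cost_params()] object.
#' @param income,employment_rate Optional overrides (per-report income
#'   vector, scalar employment rate) used by the sensitivity analyses.
#' @return Currency vector (CAD), one element per report.
#' @export
#' @examples
#' p <- cost_params()
#' hc_death_loss(64, "unknown", p) # one remaining working year: 0.75 * 46268
hc_death_loss <- function(age_years, sex, params, income = NULL,
                          employment_rate = NULL) {
  check_age(age_years)
  inc <- sex_income(sex, params, income)
  er <- employment_rate %||% params$employment_rate
  imp <- impute_unknown(age_years, params)
  ann <- working_annuity(imp$age, params$discount_rate, params$working_age)
  er * inc * ann * imp$scale
}

disability_loss_fraction <- function(params, employment_loss = NULL,
                                     income_loss = NULL) {
  e <- employment_loss %||% params$disability_employment_loss
  i <- income_loss %||% params$disability_income_loss
  switch(params$disability_decrement,
    multiplicative = 1 - (1 - e) * (1 - i),
    additive = pmin(e + i, 1)
  )
}

#' Human-capital wage loss for an ADR-related disability
#'
#' Expected annual wage loss per disabled patient is
#' `employment_rate * income * f`, where `f` combines the disability
#' employment and income decrements (multiplicatively by default). The
#' annual loss is accumulated and discounted over the remaining working
#' years exactly as in [hc_death_loss()]. When
#' `params$apply_disability_benefit` is on, the annual disability benefit is
#' subtracted from the annual loss (floored at zero) before accumulation.
#'
#' @inheritParams hc_death_loss
#' @param employment_loss,income_loss Optional decrement overrides.
#' @return Currency vector (CAD).
#' @export
hc_disability_loss <- function(age_years, sex, params, income = NULL,
                               employment_rate = NULL, employment_loss = NULL,
                               income_loss = NULL) {
  check_age(age_years)
  inc <- sex_income(sex, params, income)
  er <- employment_rate %||% params$employment_rate
  f <- disability_loss_fraction(params, employment_loss, income_loss)
  annual <- er * inc * f
  if (params$apply_disability_benefit) {
    annual <- pmax(annual - params$disability_benefit, 0)
  }
  imp <- impute_unknown(age_years, params)
  ann <- working_annuity(imp$age, params$discount_rate, params$working_age)
  annual * ann * imp$scale
}

hosp_band_value <- function(age_years, params, what = c("cost", "los")) {
  what <- match.arg(what)
  b <- params$hosp_bands
  idx <- findInterval(age_years, b$age_min)
  idx[idx < 1] <- NA_integer_
  vals <- b[[what]][idx]
  unknown <- if (what == "cost") params$hosp_cost_unknown else params$los_unknown
  ifelse(is.na(age_years), unknown, vals)
}

#' Opportunity cost of an ADR-related hospitalization
#'
#' Length of stay (from the age-band schedule, or the population average for
#' unknown age) times the employment-weighted daily wage.
#'
#' @inheritParams hc_death_loss
#' @param los Optional length-of-stay override (days, per report).
#' @return Currency vector (CAD).
#' @export
hosp_opportunity_cost <- function(age_years, sex, params, income = NULL,
                                  employment_rate = NULL, los = NULL) {
  check_age(age_years)
  inc <- sex_income(sex, params, income)
  er <- employment_rate %||% params$employment_rate
  days <- los %||% hosp_band_value(age_years, params, "los")
  days * (inc / params$daily_divisor) * er
}

#' Opportunity cost of an OMIC event (one day of lost wages)
#'
#' @inheritParams hc_death_loss
#' @return Currency vector (CAD).
#' @export
omic_opportunity_cost <- function(sex, params, income = NULL,
                                  employment_rate = NULL) {
  inc <- sex_income(sex, params, income)
  er <- employment_rate %||% params$employment_rate
  (inc / params$daily_divisor) * er
}

#' Direct healthcare cost of an ADR-related hospitalization
#'
#' Per-stay cost looked up in the age-band schedule; unknown age uses the
#' population-weighted average.
#'
#' @inheritParams hc_death_loss
#' @param cost Optional per-report cost override.
#' @return Currency vector (CAD).
#' @export
direct_hosp_cost <- function(age_years, params, cost = NULL) {
  check_age(age_years)
  cost %||% hosp_band_value(age_years, params, "cost")
}

#' Direct healthcare cost of an OMIC event
#'
#' @param params A [cost_params()] object.
#' @return The per-event unit cost (an ER visit in the base case).
#' @export
direct_omic_cost <- function(params) {
  params$omic_unit_cost
}

#' Friction-cost productivity loss
#'
#' Society loses `employment_rate * income * friction_months / 12` for each
#' working-age death (the time to replace the worker). For disability only
#' the displaced fraction (`disability_employment_loss`) vacates a job.
#' Hospitalization and OMIC events carry no friction loss. Unknown-age
#' patients are scaled by `unknown_age_working_fraction`; known ages outside
#' the working-age window contribute nothing.
#'
#' @param category `"death"`, `"disability"`, `"hospitalization"` or
#'   `"omic"`.
#' @inheritParams hc_death_loss
#' @param employment_loss Optional disability employment-loss override.
#' @return Currency vector (CAD).
#' @export
friction_loss <- function(category, age_years, sex, params, income = NULL,
                          employment_rate = NULL, employment_loss = NULL) {
  category <- match.arg(category,
                        c("death", "disability", "hospitalization", "omic"))
  if (category %in% c("hospitalization", "omic")) {
    return(numeric(max(length(age_years), length(sex))))
  }
  check_age(age_years)
  inc <- sex_income(sex, params, income)
  er <- employment_rate %||% params$employment_rate
  known <- !is.na(age_years)
  gate <- ifelse(known,
                 as.numeric(age_years >= params$working_age[1] &
                            age_years <= params$working_age[2]),
                 params$unknown_age_working_fraction)
  base <- er * inc * params$friction_months / 12 * gate
  if (category == "disability") {
    base <- base * (employment_loss %||% params$disability_employment_loss)
  }
  base
}

# ---- aggregation ----------------------------------------------------------

outcome_categories <- function() c("death", "disability", "hospitalization", "omic")

# 5-year (period) cost sums per category for each perspective component.
# `ov` may carry: income (vector), employment_rate (scalar),
# disability_employment_loss (scalar), disability_income_loss (vector),
# hosp_cost (vector), los (vector) -- all aligned with rows of `cohort`.
burden_sums <- function(cohort, params, ov = list()) {
  cats <- outcome_categories()
  zero <- setNames(numeric(4), cats)
  patient <- hs <- friction <- zero
  cat_vec <- as.character(cohort$primary_category)
  pick <- function(x, i) if (is.null(x) || length(x) == 1) x else x[i]
  for (cc in cats) {
    i <- which(cat_vec == cc)
    if (!length(i)) next
    age <- cohort$age_years[i]
    sx <- cohort$sex[i]
    inc <- pick(ov$income, i)
    er <- ov$employment_rate
    patient[cc] <- switch(cc,
      death = sum(hc_death_loss(age, sx, params, inc, er)),
      disability = sum(hc_disability_loss(age, sx, params, inc, er,
                                          ov$disability_employment_loss,
                                          pick(ov$disability_income_loss, i))),
      hospitalization = sum(hosp_opportunity_cost(age, sx, params, inc, er,
                                                  pick(ov$los, i))),
      omic = sum(omic_opportunity_cost(sx, params, inc, er))
    )
    hs[cc] <- switch(cc,
      hospitalization = sum(direct_hosp_cost(age, params, pick(ov$hosp_cost, i))),
      omic = length(i) * direct_omic_cost(params),
      0
    )
    if (cc %in% c("death", "disability")) {
      friction[cc] <- sum(friction_loss(cc, age, sx, params, inc, er,
                                        ov$disability_employment_loss))
    }
  }
  list(patient = patient, health_system = hs, friction = friction)
}

#' Annual economic burden of serious ADRs by perspective and category
#'
#' Sums per-report costs over a classified cohort, annualizes by
#' `params$period_years`, and reports the burden from three perspectives:
#' *patient* (human-capital opportunity costs), *health system* (direct
#' healthcare costs) and *societal* (friction-cost productivity losses plus
#' direct costs). Reports classified `nonserious` contribute nothing.
#'
#' @param cohort A classified report tibble (see [classify_outcomes()]) with
#'   columns `primary_category`, `age_years`, `sex`.
#' @param users A [users_estimate()] giving the mean annual number of drug
#'   recipients (denominator of the per-recipient burden).
#' @param params A [cost_params()] object.
#' @param overrides Internal: per-report/per-iteration parameter draws used
#'   by [psa()].
#' @return A `cost_breakdown`: list with `costs` (tibble of
#'   perspective x category annual costs), `totals` (annual total and
#'   per-recipient cost per perspective) and `mean_annual_users`.
#' @export
aggregate_burden <- function(cohort, users, params, overrides = list()) {
  stopifnot(inherits(params, "cost_params"))
  if (!"primary_category" %in% names(cohort)) {
    abort("`cohort` must be classified first (see classify_outcomes()).",
          class = "adrburden_domain_error")
  }
  mu <- mean_annual_users(users)
  sums <- burden_sums(cohort, params, overrides)
  ann <- function(x) x / params$period_years
  cats <- outcome_categories()
  societal <- ann(sums$friction)
  societal["hospitalization"] <- ann(sums$health_system[["hospitalization"]])
  societal["omic"] <- ann(sums$health_system[["omic"]])
  costs <- dplyr::bind_rows(
    tibble::tibble(perspective = "patient", category = cats,
                   annual_cost = unname(ann(sums$patient))),
    tibble::tibble(perspective = "health_system", category = cats,
                   annual_cost = unname(ann(sums$health_system))),
    tibble::tibble(perspective = "societal", category = cats,
                   annual_cost = unname(societal))
  )
  totals <- costs |>
    dplyr::group_by(perspective) |>
    dplyr::summarise(total = sum(annual_cost), .groups = "drop") |>
    dplyr::mutate(per_recipient = total / mu)
  structure(
    list(costs = costs, totals = totals, mean_annual_users = mu,
         period_years = params$period_years),
    class = "cost_breakdown"
  )
}

# Flatten a breakdown into a named numeric vector (used by one_way/psa).
breakdown_cells <- function(bd) {
  cells <- setNames(bd$costs$annual_cost,
                    paste(bd$costs$perspective, bd$costs$category, sep = "."))
  tot <- setNames(bd$totals$total, paste0(bd$totals$perspective, ".total"))
  pr <- setNames(bd$totals$per_recipient,
                 paste0(bd$totals$perspective, ".per_recipient"))
  c(cells, tot, pr)
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> annual average burden (CAD/year)\n")
  wide <- tidyr::pivot_wider(x$costs, names_from = "category",
                             values_from = "annual_cost")
  print(as.data.frame(wide), row.names = FALSE)
  cat("totals:\n")
  print(as.data.frame(x$totals), row.names = FALSE)
  cat(sprintf("mean annual recipients: %s\n",
              format(round(x$mean_annual_users), big.mark = ",")))
  invisible(x)
}
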