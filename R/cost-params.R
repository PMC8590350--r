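#' Base-case cost-model parameters
#'
#' Builds the full parameter set of the economic model: labour-market inputs
#' for the human-capital (HC) and friction-cost (FC) productivity
#' calculations, direct healthcare unit costs, and the bookkeeping constants
#' (working-age window, unknown-age imputation, analysis period). Defaults
#' are the 2018-CAD base case for the infliximab/adalimumab study the package
#' ships as its reference analysis; every value can be overridden.
#'
#' @param employment_rate Employment rate among working-age (19-64) adults.
#' @param income Named vector of average annual individual income (CAD/year)
#'   for `female`, `male` and `unknown` sex.
#' @param discount_rate Annual discount rate applied to future forgone income.
#' @param friction_months Friction period (months) to replace a displaced
#'   worker in the FC approach.
#' @param disability_employment_loss Average proportional loss of employment
#'   after an ADR-related disability.
#' @param disability_income_loss Average proportional loss of income among
#'   those remaining employed after a disability.
#' @param disability_benefit Annual disability benefit (CAD/year) optionally
#'   offset against the patient-perspective disability loss.
#' @param apply_disability_benefit Apply the benefit offset? Default `FALSE`:
#'   the benefit is listed among the inputs of the reference analysis but its
#'   use is not part of the base case.
#' @param hosp_bands Data frame with columns `age_min`, `age_max`, `cost`
#'   (CAD per hospital stay) and `los` (days). The default is a synthetic
#'   five-band schedule spanning the published national range for
#'   drug-poisoning hospitalizations (costs $1,766-$5,325, stays 1.2-3.9
#'   days); it stands in for the age-stratified cost file that is not
#'   publicly redistributable.
#' @param hosp_cost_unknown,los_unknown Population-weighted average cost and
#'   length of stay used when a patient's age is unknown.
#' @param omic_unit_cost Direct cost (CAD) of one "other medically important
#'   condition" (OMIC) event, costed as an emergency-room visit.
#' @param working_age Inclusive age range `(min, max)` over which forgone
#'   income accrues.
#' @param unknown_age_working_fraction Fraction of unknown-age patients
#'   assumed to be of working age (drug-specific; 0.47 for the infliximab
#'   reference cohort, 0.45 for adalimumab).
#' @param unknown_age_assumed Age (years) imputed to unknown-age patients
#'   when computing remaining working years.
#' @param period_years Number of calendar years pooled in the cohort; 5-year
#'   totals are divided by this to report annual averages.
#' @param daily_divisor Days per year used to convert annual income to a
#'   daily wage (365 calendar days by default; 260 working days is the usual
#'   alternative).
#' @param disability_decrement How the employment and income decrements
#'   combine into one wage-loss fraction: `"multiplicative"` (default,
#'   `1 - (1-e)(1-i)`) or `"additive"` (`min(e + i, 1)`).
#'
#' @return A validated list of class `cost_params`.
#' @seealso [aggregate_burden()], [read_cost_params()]
#' @export
#' @examples
#' p <- cost_params()
#' p$omic_unit_cost
cost_params <- function(employment_rate = 0.75,
                        income = c(female = 37847, male = 54690, unknown = 46268),
                        discount_rate = 0.015,
                        friction_months = 3,
                        disability_employment_loss = 0.225,
                        disability_income_loss = 0.315,
                        disability_benefit = 11506,
                        apply_disability_benefit = FALSE,
                        hosp_bands = default_hosp_bands(),
                        hosp_cost_unknown = 4205,
                        los_unknown = 2.3,
                        omic_unit_cost = 417,
                        working_age = c(19, 64),
                        unknown_age_working_fraction = 0.47,
                        unknown_age_assumed = 52,
                        period_years = 5,
                        daily_divisor = 365,
                        disability_decrement = c("multiplicative", "additive")) {
  params <- list(
    employment_rate = employment_rate,
    income = income,
    discount_rate = discount_rate,
    friction_months = friction_months,
    disability_employment_loss = disability_employment_loss,
    disability_income_loss = disability_income_loss,
    disability_benefit = disability_benefit,
    apply_disability_benefit = isTRUE(apply_disability_benefit),
    hosp_bands = tibble::as_tibble(hosp_bands),
    hosp_cost_unknown = hosp_cost_unknown,
    los_unknown = los_unknown,
    omic_unit_cost = omic_unit_cost,
    working_age = working_age,
    unknown_age_working_fraction = unknown_age_working_fraction,
    unknown_age_assumed = unknown_age_assumed,
    period_years = period_years,
    daily_divisor = daily_divisor,
    disability_decrement = match.arg(disability_decrement)
  )
  class(params) <- "cost_params"
  validate_cost_params(params)
}

#' Default synthetic age-band schedule for hospitalization cost and stay
#'
#' Five bands spanning the published range of per-stay costs and lengths of
#' stay for drug-poisoning hospitalizations. The band boundaries and interior
#' values are synthetic (the underlying age-stratified file is not
#' redistributable); only the endpoints and the population-weighted averages
#' match published figures.
#'
#' @return A tibble with columns `age_min`, `age_max`, `cost`, `los`.
#' @export
default_hosp_bands <- function() {
  tibble::tibble(
    age_min = c(0, 18, 40, 60, 80),
    age_max = c(17, 39, 59, 79, Inf),
    cost = c(1766, 2720, 3480, 4660, 5325),
    los = c(1.2, 1.8, 2.3, 3.0, 3.9)
  )
}

#' @rdname cost_params
#' @param params A `cost_params` object to validate.
#' @export
validate_cost_params <- function(params) {
  chk_prop <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort(sprintf("`%s` must be a proportion in [0, 1].", what),
            class = "adrburden_config_error")
    }
  }
  chk_pos <- function(x, what, strict = FALSE) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || (strict && any(x <= 0))) {
      abort(sprintf("`%s` must be %s.", what,
                    if (strict) "strictly positive" else "nonnegative"),
            class = "adrburden_config_error")
    }
  }
  chk_prop(params$employment_rate, "employment_rate")
  chk_prop(params$disability_employment_loss, "disability_employment_loss")
  chk_prop(params$disability_income_loss, "disability_income_loss")
  chk_prop(params$unknown_age_working_fraction, "unknown_age_working_fraction")
  chk_prop(params$discount_rate, "discount_rate")
  if (!all(c("female", "male", "unknown") %in% names(params$income))) {
    abort("`income` must be named for female, male and unknown sex.",
          class = "adrburden_config_error")
  }
  chk_pos(params$income, "income")
  chk_pos(params$friction_months, "friction_months")
  chk_pos(params$disability_benefit, "disability_benefit")
  chk_pos(params$hosp_cost_unknown, "hosp_cost_unknown")
  chk_pos(params$los_unknown, "los_unknown")
  chk_pos(params$omic_unit_cost, "omic_unit_cost")
  chk_pos(params$period_years, "period_years", strict = TRUE)
  chk_pos(params$daily_divisor, "daily_divisor", strict = TRUE)
  b <- params$hosp_bands
  if (!all(c("age_min", "age_max", "cost", "los") %in% names(b))) {
    abort("`hosp_bands` needs columns age_min, age_max, cost, los.",
          class = "adrburden_config_error")
  }
  chk_pos(b$cost, "hosp_bands$cost")
  chk_pos(b$los, "hosp_bands$los")
  if (params$working_age[1] > params$working_age[2]) {
    abort("`working_age` minimum exceeds maximum.",
          class = "adrburden_config_error")
  }
  params
}

#' Read or write cost parameters as YAML
#'
#' `read_cost_params()` reads a YAML file of overrides and merges it over the
#' package defaults; `write_cost_params()` serializes a full parameter set.
#'
#' @param path Path to a YAML file.
#' @param params A `cost_params` object.
#' @return `read_cost_params()` returns a validated `cost_params` object.
#' @export
read_cost_params <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cost parameter file not found: %s", path),
          class = "adrburden_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$income)) raw$income <- unlist(raw$income)
  if (!is.null(raw$hosp_bands)) {
    raw$hosp_bands <- dplyr::bind_rows(lapply(raw$hosp_bands, tibble::as_tibble))
    raw$hosp_bands$age_max[is.na(raw$hosp_bands$age_max)] <- Inf
  }
  if (!is.null(raw$working_age)) raw$working_age <- unlist(raw$working_age)
  do.call(cost_params, raw)
}

#' @rdname read_cost_params
#' @export
write_cost_params <- function(params, path) {
  stopifnot(inherits(params, "cost_params"))
  out <- unclass(params)
  out$income <- as.list(out$income)
  bands <- out$hosp_bands
  bands$age_max[is.infinite(bands$age_max)] <- NA
  out$hosp_bands <- lapply(seq_len(nrow(bands)), function(i) as.list(bands[i, ]))
  out$working_age <- as.list(out$working_age)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.cost_params <- function(x, ...) {
  cat("<cost_params>\n")
  cat(sprintf("  employment rate %.0f%%, discount %.1f%%/yr, friction %s months\n",
              100 * x$employment_rate, 100 * x$discount_rate, x$friction_months))
  cat(sprintf("  income (CAD/yr): F %s / M %s / unknown %s\n",
              format(x$income[["female"]], big.mark = ","),
              format(x$income[["male"]], big.mark = ","),
              format(x$income[["unknown"]], big.mark = ",")))
  cat(sprintf("  hospitalization: %d age bands, unknown-age cost $%s, LOS %.1f d\n",
              nrow(x$hosp_bands), format(x$hosp_cost_unknown, big.mark = ","),
              x$los_unknown))
  cat(sprintf("  OMIC unit cost $%d; period %d years; %s disability decrement\n",
              x$omic_unit_cost, x$period_years, x$disability_decrement))
  invisible(x)
}
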