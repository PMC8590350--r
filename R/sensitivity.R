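# One-way and probabilistic (Monte Carlo) sensitivity analyses around the
# deterministic base case.

#' Default one-way sensitivity ranges
#'
#' Discount rate 0-3%/year, friction period 1-5 months, OMIC unit cost
#' $208-$626 -- the model-uncertainty ranges of the reference analysis.
#'
#' @return Tibble with columns `parameter`, `low`, `high`.
#' @export
one_way_defaults <- function() {
  tibble::tibble(
    parameter = c("discount_rate", "friction_months", "omic_unit_cost"),
    low = c(0, 1, 208),
    high = c(0.03, 5, 626)
  )
}

#' One-way sensitivity analysis
#'
#' Re-runs the deterministic base case with one scalar parameter at each
#' bound, all others fixed.
#'
#' @inheritParams aggregate_burden
#' @param spec Tibble of `parameter`, `low`, `high` rows
#'   (see [one_way_defaults()]); `low <= high` is required.
#' @return A long tibble: `parameter`, `bound` (`"low"`/`"high"`), `value`,
#'   `perspective`, `category` (the four outcome categories plus `total`
#'   and `per_recipient`), `annual_cost`.
#' @export
one_way <- function(cohort, users, params, spec = one_way_defaults()) {
  if (any(spec$low > spec$high)) {
    abort("One-way spec needs low <= high.", class = "adrburden_config_error")
  }
  bad <- setdiff(spec$parameter, names(params))
  if (length(bad)) {
    abort(sprintf("Unknown parameter(s) in one-way spec: %s",
                  paste(bad, collapse = ", ")),
          class = "adrburden_config_error")
  }
  purrr::pmap_dfr(spec, function(parameter, low, high) {
    purrr::map2_dfr(c("low", "high"), c(low, high), function(bound, value) {
      p2 <- params
      p2[[parameter]] <- value
      p2 <- validate_cost_params(p2)
      cells <- breakdown_cells(aggregate_burden(cohort, users, p2))
      nm <- strsplit(names(cells), ".", fixed = TRUE)
      tibble::tibble(parameter = parameter, bound = bound, value = value,
                     perspective = vapply(nm, `[`, "", 1),
                     category = vapply(nm, `[`, "", 2),
                     annual_cost = unname(cells))
    })
  })
}

#' Specification of the probabilistic sensitivity analysis
#'
#' Patient-level quantities (income, hospitalization cost, length of stay,
#' disability income loss) are redrawn per report from gamma distributions
#' parameterized by their base-case mean and a coefficient of variation
#' (shape `1/CV^2`, scale `mean * CV^2`); population-level quantities
#' (employment rate, disability employment loss) are drawn once per
#' iteration from normal distributions truncated to `[0, 1]`. Default CVs
#' and sds are calibrated so each distribution's central 95% range
#' approximates the published probabilistic input ranges of the reference
#' analysis.
#'
#' @param n_iterations Monte Carlo iterations (5000 in the reference
#'   analysis).
#' @param seed Integer seed; identical specs give bit-identical results.
#' @param income_cv,hosp_cost_cv,los_cv,disability_income_loss_cv
#'   Coefficients of variation of the patient-level gamma draws.
#' @param employment_sd,disability_employment_sd Standard deviations of the
#'   population-level normal draws.
#' @param keep_draws Retain the full draw matrix in the result?
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 5000, seed = 1L,
                     income_cv = 0.11, hosp_cost_cv = 0.033, los_cv = 0.033,
                     disability_income_loss_cv = 0.04,
                     employment_sd = 0.048, disability_employment_sd = 0.043,
                     keep_draws = FALSE) {
  if (n_iterations < 1) {
    abort("`n_iterations` must be >= 1.", class = "adrburden_config_error")
  }
  cvs <- c(income_cv, hosp_cost_cv, los_cv, disability_income_loss_cv,
           employment_sd, disability_employment_sd)
  if (any(cvs < 0)) {
    abort("CVs and sds must be nonnegative.", class = "adrburden_config_error")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 income_cv = income_cv, hosp_cost_cv = hosp_cost_cv,
                 los_cv = los_cv,
                 disability_income_loss_cv = disability_income_loss_cv,
                 employment_sd = employment_sd,
                 disability_employment_sd = disability_employment_sd,
                 keep_draws = isTRUE(keep_draws)),
            class = "psa_spec")
}

rgamma_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) {
    return(if (length(mean) == 1) rep(mean, n) else mean)
  }
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

rnorm_trunc01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  pmin(pmax(rnorm(n, mean, sd), 0), 1)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' For each iteration, draws the population-level parameters once and the
#' patient-level parameters per report, recomputes the full cost breakdown,
#' and summarizes every perspective/category cell (plus totals and
#' per-recipient costs) by its mean and 2.5th/97.5th percentiles.
#'
#' @inheritParams aggregate_burden
#' @param spec A [psa_spec()].
#' @return A `psa_result`: tibble `summary` with columns `perspective`,
#'   `category`, `mean`, `p2.5`, `p97.5`; `n_iterations`; and, when
#'   requested, the full `draws` matrix (iterations x cells).
#' @export
psa <- function(cohort, users, params, spec = psa_spec()) {
  stopifnot(inherits(spec, "psa_spec"))
  n <- nrow(cohort)
  base_cells <- breakdown_cells(aggregate_burden(cohort, users, params))
  mean_income <- sex_income(cohort$sex, params)
  mean_hosp_cost <- hosp_band_value(cohort$age_years, params, "cost")
  mean_los <- hosp_band_value(cohort$age_years, params, "los")
  draws <- matrix(NA_real_, nrow = spec$n_iterations,
                  ncol = length(base_cells),
                  dimnames = list(NULL, names(base_cells)))
  withr::with_seed(spec$seed, {
    for (it in seq_len(spec$n_iterations)) {
      ov <- list(
        employment_rate = rnorm_trunc01(1, params$employment_rate,
                                        spec$employment_sd),
        disability_employment_loss = rnorm_trunc01(
          1, params$disability_employment_loss, spec$disability_employment_sd),
        income = rgamma_mean_cv(n, mean_income, spec$income_cv),
        disability_income_loss = pmin(
          rgamma_mean_cv(n, params$disability_income_loss,
                         spec$disability_income_loss_cv), 1),
        hosp_cost = rgamma_mean_cv(n, mean_hosp_cost, spec$hosp_cost_cv),
        los = rgamma_mean_cv(n, mean_los, spec$los_cv)
      )
      bd <- aggregate_burden(cohort, users, params, overrides = ov)
      draws[it, ] <- breakdown_cells(bd)
    }
  })
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  nm <- strsplit(colnames(draws), ".", fixed = TRUE)
  summary <- tibble::tibble(
    perspective = vapply(nm, `[`, "", 1),
    category = vapply(nm, `[`, "", 2),
    mean = unname(colMeans(draws)),
    `p2.5` = unname(qs[1, ]),
    `p97.5` = unname(qs[2, ])
  )
  structure(list(summary = summary, n_iterations = spec$n_iterations,
                 base_case = base_cells,
                 draws = if (spec$keep_draws) draws else NULL),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d Monte Carlo iterations\n", x$n_iterations))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
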