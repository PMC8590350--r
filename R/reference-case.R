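#' Published reference values for the infliximab/adalimumab case study
#'
#' The package ships the printed inputs and headline results of its
#' reference analysis -- the 2014-2018 Canada Vigilance cohorts for the two
#' TNF-alpha inhibitor biologics infliximab (Remicade) and adalimumab
#' (Humira) -- so that examples, tests and the reproduction script can run
#' the arithmetic end to end without the restricted microdata. All currency
#' values are 2018 CAD; burden components are annual averages in millions.
#'
#' @return A list:
#' \describe{
#'   \item{period}{Calendar years covered (2014-2018).}
#'   \item{reports}{Unique deduplicated ADR reports per drug.}
#'   \item{annual_recipients}{Mean annual drug recipients (sales divided by
#'     average annual treatment cost).}
#'   \item{avg_annual_treatment_cost}{Average annual treatment cost per
#'     patient (CAD).}
#'   \item{post_market_rates_pct}{Reported post-market rates (% of
#'     recipients) with 95% CIs for the death / serious / all rows.}
#'   \item{rct}{Trial-programme summaries: number of trials, participants,
#'     deaths, and the reported pooled RCT rates (%).}
#'   \item{burden_components_musd}{Annual base-case burden components
#'     (millions CAD) by perspective and outcome category. The societal
#'     perspective lists only the friction-cost productivity components;
#'     direct costs are shared with the health-system perspective.}
#'   \item{per_recipient_cad}{Reported per-recipient annual burden (CAD) by
#'     perspective.}
#'   \item{unknown_age_working_fraction}{Drug-specific fraction of
#'     unknown-age patients assumed to be of working age.}
#' }
#' @export
#' @examples
#' ref <- reference_case()
#' ref$reports["infliximab"] / (5 * ref$annual_recipients["infliximab"])
reference_case <- function() {
  drugs <- c("infliximab", "adalimumab")
  list(
    period = 2014:2018,
    reports = c(infliximab = 33013, adalimumab = 30056),
    annual_recipients = c(infliximab = 33358, adalimumab = 40566),
    avg_annual_treatment_cost = c(infliximab = 29500, adalimumab = 16400),
    post_market_rates_pct = tibble::tibble(
      outcome = rep(c("death", "serious", "all"), each = 2),
      drug = rep(drugs, 3),
      rate = c(0.21, 0.18, 18.9, 7.3, 19.8, 14.8),
      ci_low = c(0.09, 0.06, 15.8, 4.8, 16.8, 10.2),
      ci_high = c(0.33, 0.29, 22.1, 9.7, 22.8, 19.5)
    ),
    rct = tibble::tibble(
      drug = drugs,
      n_trials = c(14L, 33L),
      n_participants = c(2648L, 6295L),
      n_deaths = c(2L, 7L),
      death_rate_pct = c(0.01, 0.04),
      serious_rate_pct = c(13.1, 16.3),
      all_rate_pct = c(74.9, 48.7)
    ),
    burden_components_musd = tibble::tibble(
      perspective = c(rep("patient", 8), rep("health_system", 4),
                      rep("societal_friction", 4)),
      category = c(rep(c("death", "disability", "hospitalization", "omic"),
                       each = 2),
                   rep(c("hospitalization", "omic"), each = 2),
                   rep(c("death", "disability"), each = 2)),
      drug = rep(drugs, 8),
      annual_cost_musd = c(
        16.2, 12.9, 2.8, 5.8, 0.331, 0.171, 0.353, 0.134, # patient
        8.1, 4.5, 1.9, 0.763,                             # health system
        0.293, 0.277, 0.147, 0.273                        # friction
      )
    ),
    per_recipient_cad = tibble::tibble(
      perspective = rep(c("patient", "health_system", "societal"), each = 2),
      drug = rep(drugs, 3),
      per_recipient = c(590, 470, 301, 131, 314, 145)
    ),
    unknown_age_working_fraction = c(infliximab = 0.47, adalimumab = 0.45)
  )
}

#' Reference base-case burden summary from the printed components
#'
#' Sums the shipped annual burden components per perspective (societal =
#' friction-cost productivity losses + direct healthcare costs) and divides
#' by the mean annual recipients to give the per-recipient annual burden.
#'
#' @param drug `"infliximab"` or `"adalimumab"`.
#' @return Tibble with `perspective`, `total_musd`, `per_recipient_cad`.
#' @export
reference_burden_summary <- function(drug = c("infliximab", "adalimumab")) {
  drug <- match.arg(drug)
  ref <- reference_case()
  comp <- ref$burden_components_musd[ref$burden_components_musd$drug == drug, ]
  tot <- function(persp) {
    sum(comp$annual_cost_musd[comp$perspective == persp])
  }
  patient <- tot("patient")
  hs <- tot("health_system")
  societal <- tot("societal_friction") + hs
  users <- ref$annual_recipients[[drug]]
  tibble::tibble(
    perspective = c("patient", "health_system", "societal"),
    total_musd = c(patient, hs, societal),
    per_recipient_cad = c(patient, hs, societal) * 1e6 / users
  )
}
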