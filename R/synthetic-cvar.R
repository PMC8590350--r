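# Synthetic spontaneous-report generator with known ground truth, plus a
# closed-form expected-burden oracle. Every downstream stage (IO, dedup,
# filters, classification, rates, costing) is testable against the
# generating distributions without external data.

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the reporting structure of the package's reference
#' cohort: outcome-flag marginals close to the published report-level
#' frequencies (death 1.2%, disability 1.5%, hospitalization 27%, OMIC
#' 65%), a female-skewed sex mix, an age distribution peaking in the 50-59
#' decade with heavy older tails and an unknown-age share, several spelling
#' variants of one brand name, and 2014-2018 reporting years. Outcome flags
#' are drawn independently per report (except that death excludes
#' disability), so the realized non-serious share exceeds the marginal
#' `nonserious` probability -- real flags are positively correlated, which
#' the generator deliberately does not model.
#'
#' @param n_reports Number of unique reports.
#' @param duplicate_fraction Fraction of exact duplicate report rows to
#'   inject (duplicates copy all three tables' rows for the chosen ids).
#' @param years Inclusive calendar-year range of initial report dates.
#' @param drug_names Labels for the primary (study) drug of each report,
#'   including spelling variants of one brand to exercise name-combining.
#' @param p_outcome Named probabilities for `death`, `disability`,
#'   `hospitalization`, `omic`, `nonserious`. Death is drawn per report;
#'   disability only for non-deaths; hospitalization and OMIC
#'   independently. The `nonserious` entry is validated and recorded but the
#'   realized non-serious share is the complement of the serious draws.
#' @param sex_probs Probabilities for `female`, `male`, `unknown`
#'   (must sum to 1).
#' @param age_model List with `ages` (integer ages), `probs` (their
#'   distribution) and `unknown_fraction` (a distinct unknown-age state, so
#'   the working-age imputation path is exercised).
#' @param suspect_prob Probability the study drug row is labeled suspect.
#' @param multi_drug_prob Probability a report lists more than one drug.
#' @param annual_users Recipients per year (scalar or per-year vector).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 1000,
                             duplicate_fraction = 0,
                             years = 2014:2018,
                             drug_names = c("HUMIRA", "HUMIRA PEN",
                                            "HUMIRA PUSHTOUCH"),
                             p_outcome = c(death = 0.012, disability = 0.015,
                                           hospitalization = 0.27,
                                           omic = 0.65, nonserious = 0.03),
                             sex_probs = c(female = 0.58, male = 0.36,
                                           unknown = 0.06),
                             age_model = default_age_model(),
                             suspect_prob = 0.96,
                             multi_drug_prob = 0.5,
                             annual_users = 33358,
                             seed = 1L) {
  cfg <- list(n_reports = n_reports, duplicate_fraction = duplicate_fraction,
              years = years, drug_names = drug_names, p_outcome = p_outcome,
              sex_probs = sex_probs, age_model = age_model,
              suspect_prob = suspect_prob, multi_drug_prob = multi_drug_prob,
              annual_users = annual_users, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' Default age model of the synthetic generator
#'
#' A stylized decadal age distribution (uniform within decades) peaking at
#' 50-59 with substantial mass above 64 and below 19, so that roughly half
#' the known ages fall in the 19-64 working-age window, plus an 8%
#' unknown-age share.
#'
#' @return List with `ages`, `probs`, `unknown_fraction`.
#' @export
default_age_model <- function() {
  decade_w <- c(0.05, 0.10, 0.07, 0.08, 0.09, 0.17, 0.16, 0.16, 0.12)
  widths <- c(rep(10, 8), 11) # last band covers 80-90
  probs <- rep(decade_w / widths, times = widths)
  list(ages = 0:90, probs = probs / sum(probs), unknown_fraction = 0.08)
}

validate_synthetic_config <- function(cfg) {
  err <- function(msg) abort(msg, class = "adrburden_config_error")
  if (cfg$n_reports < 1) err("`n_reports` must be >= 1.")
  if (!length(cfg$years)) err("`years` must be nonempty.")
  if (cfg$duplicate_fraction < 0) err("`duplicate_fraction` must be >= 0.")
  need <- c("death", "disability", "hospitalization", "omic", "nonserious")
  if (!all(need %in% names(cfg$p_outcome))) {
    err("`p_outcome` must name death, disability, hospitalization, omic, nonserious.")
  }
  probs <- c(cfg$p_outcome, cfg$sex_probs, cfg$suspect_prob,
             cfg$multi_drug_prob, cfg$age_model$unknown_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    err("All probabilities must lie in [0, 1].")
  }
  if (abs(sum(cfg$sex_probs) - 1) > 1e-9) err("`sex_probs` must sum to 1.")
  if (!setequal(names(cfg$sex_probs), c("female", "male", "unknown"))) {
    err("`sex_probs` must be named female, male, unknown.")
  }
  am <- cfg$age_model
  if (length(am$ages) != length(am$probs) || any(am$probs < 0)) {
    err("`age_model$ages` and `$probs` must align, probs nonnegative.")
  }
  if (!length(cfg$drug_names)) err("`drug_names` must be nonempty.")
  cfg
}

concomitant_pool <- function() {
  c("METHOTREXATE", "PREDNISONE", "AZATHIOPRINE", "FOLIC ACID", "IBUPROFEN")
}

outcome_label_for <- function(flag) {
  c(death = "Death", disability = "Disability",
    hospitalization = "Hospitalization - Initial or Prolonged",
    omic = "Other Medically Important Condition")[[flag]]
}

#' Generate synthetic extract tables with ground truth
#'
#' Draws a cohort from `config`, lays it out in the same three-table format
#' [read_extract()] consumes, injects exact duplicate rows at
#' `duplicate_fraction`, and records the realized generating counts as
#' ground truth. Identical seeds give identical tables (and byte-identical
#' files through [write_extract()]).
#'
#' @param config A [synthetic_config()].
#' @return List with `tables` (a `report_tables` object) and `truth` (a
#'   `cvar_ground_truth` list of realized counts).
#' @export
generate_cvar <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_reports
  am <- config$age_model
  p <- config$p_outcome
  withr::with_seed(config$seed, {
    ids <- sprintf("RPT%07d", seq_len(n))
    year <- config$years[sample.int(length(config$years), n, replace = TRUE)]
    date <- as.Date(sprintf("%d-01-01", year)) + (sample.int(365, n, TRUE) - 1)
    sex <- sample(names(config$sex_probs), n, TRUE, prob = config$sex_probs)
    unknown_age <- stats::runif(n) < am$unknown_fraction
    age <- ifelse(unknown_age, NA_real_,
                  sample(am$ages, n, TRUE, prob = am$probs))
    f_death <- stats::runif(n) < p[["death"]]
    f_dis <- !f_death & (stats::runif(n) < p[["disability"]])
    f_hosp <- stats::runif(n) < p[["hospitalization"]]
    f_omic <- stats::runif(n) < p[["omic"]]
    serious <- f_death | f_dis | f_hosp | f_omic

    primary_drug <- sample(config$drug_names, n, TRUE)
    role <- ifelse(stats::runif(n) < config$suspect_prob, "Suspect", "Concomitant")
    multi <- stats::runif(n) < config$multi_drug_prob
    n_extra <- ifelse(multi, 1 + (stats::runif(n) < 0.4), 0)
    indication <- sample(c("Crohn's disease", "Rheumatoid arthritis",
                           "Psoriasis", "Colitis ulcerative", ""),
                         n, TRUE, prob = c(0.35, 0.20, 0.10, 0.15, 0.20))

    age_num <- age
    age_is_months <- !is.na(age_num) & age_num < 2
    reports <- tibble::tibble(
      report_id = ids,
      date_received = date,
      age = dplyr::case_when(is.na(age_num) ~ NA_character_,
                             age_is_months ~ as.character(age_num * 12),
                             TRUE ~ as.character(age_num)),
      age_unit = dplyr::case_when(is.na(age_num) ~ NA_character_,
                                  age_is_months ~ "Months",
                                  TRUE ~ "Years"),
      sex = dplyr::case_when(sex == "female" ~ "Female",
                             sex == "male" ~ "Male",
                             TRUE ~ ""),
      serious = ifelse(serious, "1", "0"),
      age_years = age_num
    )

    drugs <- tibble::tibble(report_id = ids, drug_name = primary_drug,
                            drug_role = role, indication = indication)
    extra_idx <- rep(seq_len(n), n_extra)
    if (length(extra_idx)) {
      drugs <- dplyr::bind_rows(drugs, tibble::tibble(
        report_id = ids[extra_idx],
        drug_name = sample(concomitant_pool(), length(extra_idx), TRUE),
        drug_role = "Concomitant",
        indication = ""
      ))
      drugs <- drugs[order(match(drugs$report_id, ids)), , drop = FALSE]
    }

    flag_mat <- cbind(death = f_death, disability = f_dis,
                      hospitalization = f_hosp, omic = f_omic)
    out_idx <- which(flag_mat, arr.ind = TRUE)
    outcomes <- tibble::tibble(
      report_id = ids[out_idx[, "row"]],
      outcome_label = vapply(colnames(flag_mat)[out_idx[, "col"]],
                             outcome_label_for, character(1), USE.NAMES = FALSE)
    )
    flagless <- which(!serious)
    if (length(flagless)) {
      outcomes <- dplyr::bind_rows(outcomes, tibble::tibble(
        report_id = ids[flagless], outcome_label = "Not serious"))
    }
    outcomes <- outcomes[order(match(outcomes$report_id, ids)), , drop = FALSE]

    n_dup <- round(config$duplicate_fraction * n)
    if (n_dup > 0) {
      dup_ids <- sample(ids, n_dup, replace = n_dup > n)
      dup_rows <- function(tb) {
        dplyr::bind_rows(tb, purrr::map_dfr(dup_ids, function(id) {
          tb[tb$report_id == id, , drop = FALSE]
        }))
      }
      reports <- dup_rows(reports)
      drugs <- dup_rows(drugs)
      outcomes <- dup_rows(outcomes)
    }
  })

  primary <- rep("nonserious", n)
  primary[f_omic] <- "omic"
  primary[f_hosp] <- "hospitalization"
  primary[f_dis] <- "disability"
  primary[f_death] <- "death"

  year_counts <- vapply(config$years, function(y) sum(year == y), numeric(1))
  truth <- structure(list(
    n_reports = n,
    reports_per_year = tibble::tibble(year = config$years, n = year_counts),
    flag_counts = c(death = sum(f_death), disability = sum(f_dis),
                    hospitalization = sum(f_hosp), omic = sum(f_omic),
                    serious = sum(serious), nonserious = sum(!serious)),
    primary_counts = table(factor(primary, levels = c(outcome_categories(),
                                                      "nonserious"))),
    drug_counts = tibble::tibble(drug_name = config$drug_names,
                                 n = vapply(config$drug_names,
                                            function(d) sum(primary_drug == d),
                                            numeric(1))),
    suspect_count = sum(role == "Suspect"),
    sex_counts = table(factor(sex, levels = c("female", "male", "unknown"))),
    unknown_age_count = sum(unknown_age),
    annual_users = config$annual_users,
    years = config$years,
    seed = config$seed
  ), class = "cvar_ground_truth")

  tables <- structure(list(reports = reports, drugs = drugs,
                           outcomes = outcomes, dialect = cvar_dialect()),
                      class = "report_tables")
  list(tables = tables, truth = truth)
}

#' Write generator ground truth as YAML
#'
#' @param truth A `cvar_ground_truth` from [generate_cvar()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- lapply(unclass(truth), function(x) {
    if (inherits(x, "tbl_df")) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else if (inherits(x, "table")) as.list(setNames(as.numeric(x), names(x)))
    else if (!is.null(names(x))) as.list(x)
    else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- closed-form oracle ---------------------------------------------------

# Expected per-event unit costs, written independently of the costing code
# path: explicit year-by-year accumulation instead of the annuity closed
# form, and direct band scans instead of findInterval.
oracle_unit_costs <- function(params) {
  wa <- params$working_age
  r <- params$discount_rate
  ann <- function(a) {
    if (a > wa[2]) return(0)
    total <- 0
    for (offset in 0:(wa[2] - a)) {
      if (a + offset >= wa[1]) total <- total + (1 + r)^(-offset)
    }
    total
  }
  band_val <- function(a, what) {
    b <- params$hosp_bands
    for (i in seq_len(nrow(b))) {
      if (a >= b$age_min[i] && a <= b$age_max[i]) return(b[[what]][i])
    }
    stop("age outside all bands")
  }
  er <- params$employment_rate
  lf <- disability_loss_fraction(params)
  list(
    death = function(a, inc) {
      if (is.na(a)) {
        params$unknown_age_working_fraction * er * inc * ann(params$unknown_age_assumed)
      } else er * inc * ann(a)
    },
    disability = function(a, inc) {
      annual <- er * inc * lf
      if (params$apply_disability_benefit) {
        annual <- max(annual - params$disability_benefit, 0)
      }
      if (is.na(a)) {
        params$unknown_age_working_fraction * annual * ann(params$unknown_age_assumed)
      } else annual * ann(a)
    },
    hosp_opp = function(a, inc) {
      los <- if (is.na(a)) params$los_unknown else band_val(a, "los")
      los * inc / params$daily_divisor * er
    },
    omic_opp = function(a, inc) inc / params$daily_divisor * er,
    hosp_direct = function(a, inc) {
      if (is.na(a)) params$hosp_cost_unknown else band_val(a, "cost")
    },
    omic_direct = function(a, inc) params$omic_unit_cost,
    friction_death = function(a, inc) {
      gate <- if (is.na(a)) params$unknown_age_working_fraction
              else as.numeric(a >= wa[1] && a <= wa[2])
      er * inc * params$friction_months / 12 * gate
    },
    friction_disability = function(a, inc) {
      gate <- if (is.na(a)) params$unknown_age_working_fraction
              else as.numeric(a >= wa[1] && a <= wa[2])
      er * inc * params$friction_months / 12 * gate *
        params$disability_employment_loss
    }
  )
}

#' Closed-form expected annual burden under a generator configuration
#'
#' Computes `E[annual cost]` per outcome category and perspective
#' analytically: primary-category probabilities follow from the generator's
#' flag scheme (death excludes disability; precedence death > disability >
#' hospitalization > OMIC), and per-event unit costs are averaged over the
#' configured age and sex distributions on a discrete grid. The computation
#' shares no code with the pipeline's classification or aggregation path,
#' so it serves as an independent oracle for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param params A [cost_params()]; its `period_years` should equal the
#'   number of generated reporting years for a like-for-like comparison.
#' @return List with `category_prob`, expected annual `costs` per
#'   perspective/category, `totals` and `per_recipient` per perspective.
#' @export
expected_burden_oracle <- function(config, params) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "cost_params"))
  p <- config$p_outcome
  pd <- p[["death"]]; pdis <- p[["disability"]]
  ph <- p[["hospitalization"]]; po <- p[["omic"]]
  category_prob <- c(
    death = pd,
    disability = (1 - pd) * pdis,
    hospitalization = (1 - pd) * (1 - pdis) * ph,
    omic = (1 - pd) * (1 - pdis) * (1 - ph) * po
  )
  am <- config$age_model
  u <- am$unknown_fraction
  ages <- c(am$ages, NA_real_)
  age_w <- c((1 - u) * am$probs, u)
  sex_w <- config$sex_probs[c("female", "male", "unknown")]
  incomes <- params$income[c("female", "male", "unknown")]
  fns <- oracle_unit_costs(params)
  e_unit <- vapply(fns, function(f) {
    grid <- outer(seq_along(ages), seq_along(sex_w),
                  Vectorize(function(i, j) f(ages[i], incomes[[j]])))
    sum(grid * outer(age_w, as.numeric(sex_w)))
  }, numeric(1))
  n_annual <- config$n_reports / params$period_years
  exp_cost <- function(unit, cat) n_annual * category_prob[[cat]] * unit
  patient <- c(death = exp_cost(e_unit[["death"]], "death"),
               disability = exp_cost(e_unit[["disability"]], "disability"),
               hospitalization = exp_cost(e_unit[["hosp_opp"]], "hospitalization"),
               omic = exp_cost(e_unit[["omic_opp"]], "omic"))
  health_system <- c(death = 0, disability = 0,
                     hospitalization = exp_cost(e_unit[["hosp_direct"]],
                                                "hospitalization"),
                     omic = exp_cost(e_unit[["omic_direct"]], "omic"))
  friction <- c(death = exp_cost(e_unit[["friction_death"]], "death"),
                disability = exp_cost(e_unit[["friction_disability"]],
                                      "disability"),
                hospitalization = 0, omic = 0)
  societal <- friction + health_system
  totals <- c(patient = sum(patient), health_system = sum(health_system),
              societal = sum(societal))
  mu <- mean(config$annual_users)
  list(category_prob = category_prob,
       costs = list(patient = patient, health_system = health_system,
                    societal = societal),
       totals = totals,
       per_recipient = totals / mu)
}
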