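# End-to-end orchestration: one configuration drives simulation/ingestion,
# cohort construction, rates, meta-analysis, costing and sensitivity
# analyses, and writes the tabular artifacts.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file. Recognized top-level keys match the arguments of
#'   [run_pipeline()]'s config list.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Run configuration not found: %s", path),
          class = "adrburden_config_error")
  }
  yaml::read_yaml(path)
}

resolve_params <- function(config) {
  cp <- config$cost_params
  if (is.null(cp)) return(cost_params())
  if (is.character(cp)) return(read_cost_params(cp))
  do.call(cost_params, cp)
}

#' Run the ADR burden pipeline end to end
#'
#' Executes, in order: data acquisition (synthetic generation or extract
#' ingestion), join/dedup, drug and period filters, outcome classification,
#' descriptive summary, recipients estimate, post-market rate table
#' (optionally joined with pooled RCT rates and fold differences),
#' base-case burden, one-way sensitivity analysis and PSA, writing each
#' stage's table as CSV plus a `run_metadata.yaml` that fully determines
#' the outputs. All randomness derives from the single `seed` entry.
#'
#' @param config A list (or path to a YAML file, see [read_run_config()])
#'   with entries:
#'   \describe{
#'     \item{simulate}{List of [synthetic_config()] arguments, or `NULL` to
#'       read real extracts from `extract` (named paths + optional
#'       `dialect = "csv"`).}
#'     \item{drug_patterns}{Substrings selecting the study drug.}
#'     \item{period}{`c(start_year, end_year)`.}
#'     \item{users}{Either `annual_users`, or `annual_sales` +
#'       `avg_annual_cost`.}
#'     \item{trial_arms}{Optional CSV path of RCT arm summaries.}
#'     \item{cost_params}{Path to a YAML parameter file, a list of
#'       overrides, or `NULL` for defaults.}
#'     \item{one_way}{`FALSE`, `TRUE` (defaults) or a spec tibble/list.}
#'     \item{psa}{`FALSE` or a list of [psa_spec()] arguments.}
#'     \item{outdir}{Output directory.}
#'     \item{seed}{Root integer seed.}
#'   }
#' @return Invisibly, a list with every stage result and the written file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% abort("Config needs an `outdir`.",
                                     class = "adrburden_config_error")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  params <- resolve_params(config)

  # --- data -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    scfg <- do.call(synthetic_config, sim_args)
    gen <- generate_cvar(scfg)
    tables <- gen$tables
    truth <- gen$truth
  } else {
    paths <- config$extract
    if (is.null(paths)) {
      abort("Config needs either `simulate` or `extract` paths.",
            class = "adrburden_config_error")
    }
    dialect <- if (identical(paths$dialect, "csv")) {
      cvar_dialect(delim = ",", header = TRUE)
    } else cvar_dialect()
    tables <- read_extract(paths, dialect)
    truth <- NULL
  }

  reports <- join_and_dedup(tables)
  if (!is.null(config$drug_patterns)) {
    reports <- filter_drug(reports, config$drug_patterns)
  }
  if (!is.null(config$period)) {
    reports <- filter_period(reports, config$period[1], config$period[2])
  }
  cohort <- classify_outcomes(reports)
  summary <- summarize_cohort(cohort, drug_patterns = config$drug_patterns)

  years <- if (!is.null(config$period)) {
    seq(config$period[1], config$period[2])
  } else {
    sort(unique(as.integer(format(cohort$initial_report_date, "%Y"))))
  }
  uc <- config$users %||% list()
  users <- if (!is.null(uc$annual_users)) {
    users_estimate(unlist(uc$annual_users), years)
  } else if (!is.null(uc$annual_sales)) {
    estimate_users(unlist(uc$annual_sales), uc$avg_annual_cost, years)
  } else if (!is.null(truth)) {
    users_estimate(unlist(truth$annual_users), years)
  } else {
    abort("Config needs `users` (annual_users or annual_sales + avg_annual_cost).",
          class = "adrburden_config_error")
  }

  # --- rates ----------------------------------------------------------
  rates <- rate_table(cohort, users)
  meta <- NULL
  if (!is.null(config$trial_arms)) {
    arms <- read_trial_arms(config$trial_arms)
    meta <- purrr::imap_dfr(
      c(death = "deaths", serious = "serious", all = "all_ae"),
      function(field, nm) {
        m <- dl_pool(arms, field)
        tibble::tibble(outcome = nm, rct_rate = m$pooled,
                       rct_ci_low = m$ci_low, rct_ci_high = m$ci_high,
                       rct_tau2 = m$tau2, rct_I2 = m$I2, rct_k = m$k,
                       rct_significant = m$significant)
      })
    rates <- dplyr::left_join(rates, meta, by = "outcome")
    rates$fold_difference <- ifelse(rates$rct_rate > 0,
                                    rates$rate / rates$rct_rate, NA_real_)
  }

  # --- burden ---------------------------------------------------------
  base <- aggregate_burden(cohort, users, params)
  ow <- NULL
  if (!isFALSE(config$one_way)) {
    ow_spec <- if (is.null(config$one_way) || isTRUE(config$one_way)) {
      one_way_defaults()
    } else tibble::as_tibble(config$one_way)
    ow <- one_way(cohort, users, params, ow_spec)
  }
  psa_res <- NULL
  if (!isFALSE(config$psa)) {
    psa_args <- if (is.list(config$psa)) config$psa else list()
    psa_args$seed <- psa_args$seed %||% (seed + 1L)
    psa_res <- psa(cohort, users, params, do.call(psa_spec, psa_args))
  }

  # --- artifacts ------------------------------------------------------
  paths <- c(
    cohort_summary = file.path(outdir, "cohort_summary.csv"),
    rates = file.path(outdir, "rates.csv"),
    burden_base = file.path(outdir, "burden_base.csv"),
    run_metadata = file.path(outdir, "run_metadata.yaml")
  )
  write_cohort_summary(summary, paths[["cohort_summary"]])
  readr::write_csv(rates, paths[["rates"]])
  base_tbl <- dplyr::bind_rows(
    base$costs,
    tibble::tibble(perspective = base$totals$perspective, category = "total",
                   annual_cost = base$totals$total),
    tibble::tibble(perspective = base$totals$perspective,
                   category = "per_recipient",
                   annual_cost = base$totals$per_recipient)
  )
  readr::write_csv(base_tbl, paths[["burden_base"]])
  if (!is.null(ow)) {
    paths[["burden_oneway"]] <- file.path(outdir, "burden_oneway.csv")
    readr::write_csv(ow, paths[["burden_oneway"]])
  }
  if (!is.null(psa_res)) {
    paths[["burden_psa"]] <- file.path(outdir, "burden_psa.csv")
    readr::write_csv(psa_res$summary, paths[["burden_psa"]])
  }
  meta_out <- list(
    package_version = as.character(utils::packageVersion("adrburden")),
    seed = seed,
    period = years,
    drug_patterns = config$drug_patterns,
    mean_annual_users = mean_annual_users(users),
    n_reports = nrow(cohort),
    rate_ci_method = unique(rates$conf_method),
    cost_params = list(
      discount_rate = params$discount_rate,
      friction_months = params$friction_months,
      daily_divisor = params$daily_divisor,
      disability_decrement = params$disability_decrement,
      apply_disability_benefit = params$apply_disability_benefit,
      period_years = params$period_years
    )
  )
  yaml::write_yaml(meta_out, paths[["run_metadata"]])

  invisible(list(tables = tables, truth = truth, cohort = cohort,
                 summary = summary, users = users, rates = rates,
                 meta = meta, base = base, one_way = ow, psa = psa_res,
                 params = params, paths = paths))
}
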