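# Cohort construction: drug/period filters, outcome classification, and
# descriptive summaries.

#' Default outcome-label dictionary
#'
#' Maps (lower-cased) outcome labels as they appear in spontaneous-report
#' extracts to the model's outcome flags. Label spellings vary by extract
#' vintage, so the dictionary is data, not code: pass your own named vector
#' to [classify_outcomes()] to extend it.
#'
#' @return Named character vector: names are lower-cased labels, values are
#'   flags among `death`, `disability`, `hospitalization`, `omic`,
#'   `nonserious`.
#' @export
default_label_map <- function() {
  c(
    "death" = "death",
    "disability" = "disability",
    "hospitalization - initial or prolonged" = "hospitalization",
    "hospitalization" = "hospitalization",
    "other medically important condition" = "omic",
    "omic" = "omic",
    "not serious" = "nonserious",
    "nonserious" = "nonserious"
  )
}

#' Keep reports mentioning a drug of interest
#'
#' Case-insensitive substring matching of every drug name in a report
#' against a set of patterns, regardless of the drug's suspect/concomitant
#' role. Combining several spelling variants of one brand is the intended
#' use (pass all variants as patterns).
#'
#' @param reports A deduplicated report tibble (see [join_and_dedup()]).
#' @param name_patterns Character vector of (fixed, not regex) substrings.
#' @return The filtered tibble.
#' @export
#' @examples
#' # patterns c("humira") match a drug named "HUMIRA PEN"
filter_drug <- function(reports, name_patterns) {
  if (!length(name_patterns)) {
    abort("`name_patterns` must be a nonempty character vector.",
          class = "adrburden_domain_error")
  }
  pats <- tolower(name_patterns)
  keep <- purrr::map_lgl(reports$drugs, function(d) {
    if (is.null(d) || !nrow(d)) return(FALSE)
    nm <- tolower(d$name)
    any(vapply(pats, function(p) any(grepl(p, nm, fixed = TRUE)), logical(1)))
  })
  reports[keep, , drop = FALSE]
}

#' Keep reports initially received within a year window
#'
#' @param reports A deduplicated report tibble.
#' @param start_year,end_year Inclusive calendar-year bounds on the initial
#'   report date.
#' @return The filtered tibble.
#' @export
filter_period <- function(reports, start_year, end_year) {
  if (start_year > end_year) {
    abort("`start_year` must not exceed `end_year`.",
          class = "adrburden_domain_error")
  }
  yr <- as.integer(format(reports$initial_report_date, "%Y"))
  reports[!is.na(yr) & yr >= start_year & yr <= end_year, , drop = FALSE]
}

#' Classify reports into outcome categories
#'
#' Maps each report's outcome labels through the label dictionary into raw
#' flags, then assigns a single *primary* category by precedence (default
#' death > disability > hospitalization > omic > nonserious) so that each
#' report is costed exactly once. Raw flags are kept for rate tabulation,
#' where a report may legitimately count under several outcomes. Unmapped
#' labels are treated as nonserious and counted in the
#' `"unmapped_labels"` attribute.
#'
#' @param reports A deduplicated report tibble.
#' @param label_map Named character vector, see [default_label_map()].
#' @param precedence Character vector ordering the serious categories.
#' @return `reports` with added logical columns `flag_death`,
#'   `flag_disability`, `flag_hospitalization`, `flag_omic` and a factor
#'   column `primary_category`.
#' @export
classify_outcomes <- function(reports, label_map = default_label_map(),
                              precedence = c("death", "disability",
                                             "hospitalization", "omic")) {
  stopifnot(setequal(precedence, c("death", "disability", "hospitalization", "omic")))
  unmapped <- character(0)
  flags <- purrr::map(reports$outcome_labels, function(labs) {
    if (!length(labs)) return(character(0))
    key <- tolower(trimws(labs))
    hit <- label_map[key]
    unmapped <<- c(unmapped, labs[is.na(hit)])
    unique(hit[!is.na(hit)])
  })
  if (length(unmapped)) {
    inform(sprintf("classify_outcomes: %d unmapped outcome label(s) treated as nonserious (e.g. %s).",
                   length(unmapped), paste(head(unique(unmapped), 3), collapse = ", ")))
  }
  for (cc in c("death", "disability", "hospitalization", "omic")) {
    reports[[paste0("flag_", cc)]] <- purrr::map_lgl(flags, ~ cc %in% .x)
  }
  primary <- rep("nonserious", nrow(reports))
  for (cc in rev(precedence)) {
    primary[reports[[paste0("flag_", cc)]]] <- cc
  }
  reports$primary_category <- factor(primary,
                                     levels = c(precedence, "nonserious"))
  attr(reports, "unmapped_labels") <- table(unmapped)
  reports
}

age_band_decadal <- function(age_years) {
  cut(age_years, breaks = c(seq(0, 80, by = 10), Inf), right = FALSE,
      labels = c(paste(seq(0, 70, 10), seq(9, 79, 10), sep = "-"), "80+"))
}

#' Descriptive summary of a classified cohort
#'
#' Tabulates the cohort by sex, decadal age band, raw outcome flag,
#' indication (over reports that list one) and reporting year, and computes
#' the fraction of reports where the study drug is labeled suspect.
#'
#' @param reports A classified report tibble.
#' @param drug_patterns Optional patterns identifying the study drug; when
#'   given, the suspect fraction counts reports where a *matching* drug has
#'   the suspect role, otherwise any drug counts.
#' @return A `cohort_summary` list of tibbles.
#' @export
summarize_cohort <- function(reports, drug_patterns = NULL) {
  n <- nrow(reports)
  count_tbl <- function(x, name) {
    tb <- tibble::as_tibble(table(x, useNA = "no"))
    names(tb) <- c(name, "n")
    tb$fraction <- tb$n / n
    tb
  }
  by_sex <- count_tbl(reports$sex, "sex")
  band <- as.character(age_band_decadal(reports$age_years))
  band[is.na(band)] <- "unknown"
  by_age_band <- count_tbl(band, "age_band")
  flags <- c(death = sum(reports$flag_death),
             disability = sum(reports$flag_disability),
             hospitalization = sum(reports$flag_hospitalization),
             omic = sum(reports$flag_omic),
             nonserious = sum(reports$primary_category == "nonserious"))
  by_outcome <- tibble::tibble(outcome = names(flags), n = unname(flags),
                               fraction = unname(flags) / n)
  inds <- unlist(reports$indications)
  with_ind <- sum(purrr::map_int(reports$indications, length) > 0)
  by_indication <- if (length(inds)) {
    tb <- tibble::as_tibble(table(inds))
    names(tb) <- c("indication", "n")
    tb$fraction <- tb$n / with_ind
    dplyr::arrange(tb, dplyr::desc(n))
  } else {
    tibble::tibble(indication = character(0), n = integer(0),
                   fraction = numeric(0))
  }
  suspect <- purrr::map_lgl(reports$drugs, function(d) {
    if (is.null(d) || !nrow(d)) return(FALSE)
    rows <- if (is.null(drug_patterns)) rep(TRUE, nrow(d)) else {
      nm <- tolower(d$name)
      vapply(seq_len(nrow(d)), function(i) {
        any(vapply(tolower(drug_patterns),
                   function(p) grepl(p, nm[i], fixed = TRUE), logical(1)))
      }, logical(1))
    }
    any(tolower(d$role[rows]) == "suspect")
  })
  yr <- as.integer(format(reports$initial_report_date, "%Y"))
  per_year <- count_tbl(yr, "year")
  per_year$year <- as.integer(per_year$year)
  structure(list(n = n, by_sex = by_sex, by_age_band = by_age_band,
                 by_outcome = by_outcome, by_indication = by_indication,
                 suspect_fraction = mean(suspect), per_year = per_year),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d reports; %.1f%% list the drug as suspect\n",
              x$n, 100 * x$suspect_fraction))
  cat("outcome flags:\n")
  print(as.data.frame(x$by_outcome), row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary to CSV
#'
#' Flattens the summary sections into one long CSV with a `section` column.
#'
#' @param summary A `cohort_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  sec <- function(tb, section) {
    names(tb)[1] <- "key"
    tb$key <- as.character(tb$key)
    dplyr::bind_cols(tibble::tibble(section = section), tb)
  }
  out <- dplyr::bind_rows(
    sec(summary$by_sex, "sex"),
    sec(summary$by_age_band, "age_band"),
    sec(summary$by_outcome, "outcome"),
    sec(summary$by_indication, "indication"),
    sec(summary$per_year, "year"),
    tibble::tibble(section = "suspect", key = "suspect_fraction",
                   n = NA_integer_, fraction = summary$suspect_fraction)
  )
  readr::write_csv(out, path)
  invisible(path)
}
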