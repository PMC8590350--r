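# Reading/writing spontaneous-report extract tables and collapsing them to
# one record per report. The default dialect mirrors public Canada
# Vigilance-style extracts: '$'-delimited text without a header row, column
# order fixed by an explicit column map; a CSV-with-header dialect is also
# supported.

report_columns <- function() {
  list(
    reports = c("report_id", "date_received", "age", "age_unit", "sex", "serious"),
    drugs = c("report_id", "drug_name", "drug_role", "indication"),
    outcomes = c("report_id", "outcome_label")
  )
}

#' Extract-table dialect
#'
#' Describes how the three extract tables (reports, report-drug links,
#' outcomes) are serialized: delimiter, header presence, column names (the
#' column map, required when files carry no header), date format and
#' encoding.
#'
#' @param delim Field delimiter. `"$"` by default.
#' @param header Do files carry a header row?
#' @param col_names Named list of character vectors giving the column order
#'   of each table when `header = FALSE` (and validated against the header
#'   otherwise).
#' @param date_format `strptime`-style format of `date_received`.
#' @param encoding Character encoding of the files.
#' @return An object of class `cvar_dialect`.
#' @export
#' @examples
#' cvar_dialect() # public-extract style
#' cvar_dialect(delim = ",", header = TRUE) # CSV dialect
cvar_dialect <- function(delim = "$", header = FALSE,
                         col_names = report_columns(),
                         date_format = "%Y-%m-%d", encoding = "UTF-8") {
  structure(list(delim = delim, header = header, col_names = col_names,
                 date_format = date_format, encoding = encoding),
            class = "cvar_dialect")
}

read_one_table <- function(path, what, dialect) {
  if (!file.exists(path)) {
    abort(sprintf("Extract file not found: %s", path),
          class = "adrburden_format_error")
  }
  wanted <- dialect$col_names[[what]]
  tb <- readr::read_delim(
    path, delim = dialect$delim,
    col_names = if (dialect$header) TRUE else wanted,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = dialect$encoding),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(wanted, names(tb))
  if (length(missing)) {
    abort(sprintf("Table '%s' (%s) is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "adrburden_format_error")
  }
  tb[wanted]
}

normalize_age_years <- function(age, unit) {
  v <- suppressWarnings(as.numeric(age))
  u <- tolower(trimws(ifelse(is.na(unit), "", unit)))
  mult <- dplyr::case_when(
    u %in% c("", "year", "years", "yr", "y") ~ 1,
    u %in% c("month", "months", "mo") ~ 1 / 12,
    u %in% c("decade", "decades") ~ 10,
    TRUE ~ NA_real_
  )
  out <- v * mult
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

normalize_sex <- function(sex) {
  s <- tolower(trimws(ifelse(is.na(sex), "", sex)))
  dplyr::case_when(
    s %in% c("female", "f") ~ "female",
    s %in% c("male", "m") ~ "male",
    TRUE ~ "unknown"
  )
}

#' Read a set of CVAR-style extract tables
#'
#' Reads the three delimited tables, types and validates them, and parses
#' dates and ages. Rows whose `date_received` cannot be parsed are removed,
#' counted, and reported both as a message and in the `"rejections"`
#' attribute of the result -- they are never silently dropped.
#'
#' @param paths Named list/vector with elements `reports`, `drugs`,
#'   `outcomes` giving file paths.
#' @param dialect A [cvar_dialect()].
#' @return A `report_tables` list of tibbles (`reports`, `drugs`,
#'   `outcomes`). `reports` gains parsed `date_received` (Date) and a
#'   derived `age_years` column (age normalized from years/months/decades;
#'   `NA` when missing or implausible).
#' @export
read_extract <- function(paths, dialect = cvar_dialect()) {
  stopifnot(all(c("reports", "drugs", "outcomes") %in% names(paths)))
  reports <- read_one_table(paths[["reports"]], "reports", dialect)
  drugs <- read_one_table(paths[["drugs"]], "drugs", dialect)
  outcomes <- read_one_table(paths[["outcomes"]], "outcomes", dialect)

  parsed <- as.Date(reports$date_received, format = dialect$date_format)
  bad <- is.na(parsed) & !is.na(reports$date_received) & nrow(reports) > 0
  rejections <- reports[bad, , drop = FALSE]
  if (any(bad)) {
    inform(sprintf("read_extract: dropped %d report row(s) with unparseable dates.",
                   sum(bad)))
  }
  reports <- reports[!bad, , drop = FALSE]
  reports$date_received <- parsed[!bad]
  reports$age_years <- normalize_age_years(reports$age, reports$age_unit)

  out <- structure(list(reports = reports, drugs = drugs, outcomes = outcomes,
                        dialect = dialect),
                   class = "report_tables")
  attr(out, "rejections") <- rejections
  out
}

#' Write a set of extract tables
#'
#' Inverse of [read_extract()]: serializes the three tables in the given
#' dialect (dates formatted with the dialect's date format; the derived
#' `age_years` column is not written). Writing then re-reading valid tables
#' round-trips byte-identically.
#'
#' @param tables A `report_tables` object.
#' @param dir Output directory (created if needed).
#' @param dialect A [cvar_dialect()].
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_extract <- function(tables, dir, dialect = cvar_dialect()) {
  stopifnot(inherits(tables, "report_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect$delim == ",") "csv" else "txt"
  paths <- c(reports = file.path(dir, paste0("reports.", ext)),
             drugs = file.path(dir, paste0("report_drug.", ext)),
             outcomes = file.path(dir, paste0("outcomes.", ext)))
  rep_out <- tables$reports[report_columns()$reports]
  if (inherits(rep_out$date_received, "Date")) {
    rep_out$date_received <- format(rep_out$date_received, dialect$date_format)
  }
  wr <- function(tb, path) {
    readr::write_delim(tb, path, delim = dialect$delim,
                       col_names = dialect$header, na = "")
  }
  wr(rep_out, paths[["reports"]])
  wr(tables$drugs[report_columns()$drugs], paths[["drugs"]])
  wr(tables$outcomes[report_columns()$outcomes], paths[["outcomes"]])
  invisible(paths)
}

first_informative <- function(x) {
  y <- x[!is.na(x) & !(is.character(x) & x == "")]
  if (length(y)) y[1] else x[1]
}

#' Join extract tables on the report identifier and deduplicate
#'
#' Collapses the three tables to one row per unique `report_id`. Exact
#' duplicate rows are dropped; when duplicate rows of one report conflict,
#' the first non-missing value in file order wins and the conflict is
#' counted. Child rows (drugs/outcomes) whose `report_id` has no parent
#' report are excluded and counted. The operation is idempotent.
#'
#' @param tables A `report_tables` object from [read_extract()] or
#'   [generate_cvar()].
#' @return A tibble of deduplicated reports, one row per `report_id`, with
#'   columns `report_id`, `initial_report_date`, `age_years`, `sex`, and
#'   list-columns `drugs` (tibble of name/role), `indications`,
#'   `outcome_labels`. Attributes `n_conflicts` and `n_orphans` carry the
#'   bookkeeping counts.
#' @export
join_and_dedup <- function(tables) {
  stopifnot(inherits(tables, "report_tables"))
  rep <- dplyr::distinct(tables$reports)
  if (!"age_years" %in% names(rep)) {
    rep$age_years <- normalize_age_years(rep$age, rep$age_unit)
  }
  if (!inherits(rep$date_received, "Date")) {
    rep$date_received <- as.Date(rep$date_received,
                                 format = tables$dialect$date_format %||% "%Y-%m-%d")
  }
  dup_ids <- unique(rep$report_id[duplicated(rep$report_id)])
  n_conflicts <- length(dup_ids)
  if (n_conflicts) {
    inform(sprintf(
      "join_and_dedup: %d report id(s) had conflicting duplicate rows; kept first non-missing values.",
      n_conflicts))
    rep <- rep |>
      dplyr::group_by(report_id) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), first_informative),
                       .groups = "drop")
  }
  # preserve first-appearance order of report ids
  ord <- match(unique(tables$reports$report_id), rep$report_id)
  rep <- rep[ord[!is.na(ord)], , drop = FALSE]

  ids <- rep$report_id
  drugs <- dplyr::distinct(tables$drugs)
  outcomes <- dplyr::distinct(tables$outcomes)
  n_orphans <- sum(!drugs$report_id %in% ids) + sum(!outcomes$report_id %in% ids)
  if (n_orphans) {
    inform(sprintf("join_and_dedup: excluded %d orphan child row(s).", n_orphans))
  }
  drugs <- drugs[drugs$report_id %in% ids, , drop = FALSE]
  outcomes <- outcomes[outcomes$report_id %in% ids, , drop = FALSE]

  f <- function(x, id) split(x, factor(id, levels = ids))
  drug_split <- f(drugs[c("drug_name", "drug_role")], drugs$report_id)
  ind_split <- f(drugs$indication, drugs$report_id)
  out_split <- f(outcomes$outcome_label, outcomes$report_id)

  res <- tibble::tibble(
    report_id = ids,
    initial_report_date = rep$date_received,
    age_years = rep$age_years,
    sex = normalize_sex(rep$sex),
    drugs = lapply(drug_split, function(d) {
      tibble::tibble(name = d$drug_name, role = tolower(d$drug_role))
    }),
    indications = lapply(ind_split, function(x) {
      unique(x[!is.na(x) & x != ""])
    }),
    outcome_labels = lapply(out_split, function(x) unique(x[!is.na(x)]))
  )
  attr(res, "n_conflicts") <- n_conflicts
  attr(res, "n_orphans") <- n_orphans
  res
}

# Inverse of join_and_dedup for round-trip/property tests: rebuilds a
# report_tables object (one reports row per report; child rows expanded).
tables_from_reports <- function(reports, dialect = cvar_dialect()) {
  rep <- tibble::tibble(
    report_id = reports$report_id,
    date_received = reports$initial_report_date,
    age = ifelse(is.na(reports$age_years), NA_character_,
                 as.character(reports$age_years)),
    age_unit = ifelse(is.na(reports$age_years), NA_character_, "Years"),
    sex = reports$sex,
    serious = NA_character_,
    age_years = reports$age_years
  )
  drugs <- purrr::map2_dfr(reports$report_id, reports$drugs, function(id, d) {
    if (!nrow(d)) return(NULL)
    tibble::tibble(report_id = id, drug_name = d$name, drug_role = d$role,
                   indication = NA_character_)
  })
  outcomes <- purrr::map2_dfr(reports$report_id, reports$outcome_labels,
                              function(id, labs) {
    if (!length(labs)) return(NULL)
    tibble::tibble(report_id = id, outcome_label = labs)
  })
  structure(list(reports = rep, drugs = drugs, outcomes = outcomes,
                 dialect = dialect),
            class = "report_tables")
}
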