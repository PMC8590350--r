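# Exposure denominator (recipients from sales) and post-market outcome
# rates with confidence intervals.

new_users_estimate <- function(by_year, source = NULL) {
  structure(list(by_year = by_year,
                 mean_annual_users = mean(by_year$users),
                 source = source),
            class = "users_estimate")
}

#' Estimate annual drug recipients from sales
#'
#' Divides each year's total sales by the average annual treatment cost per
#' patient, rounding to the nearest whole recipient.
#'
#' @param annual_sales Numeric vector of total sales (currency) per year.
#' @param avg_annual_cost Average annual treatment cost per patient
#'   (currency); must be positive.
#' @param years Optional calendar years labelling `annual_sales`.
#' @return A `users_estimate`: tibble `by_year` (`year`, `users`),
#'   `mean_annual_users`, and the `source` inputs.
#' @export
#' @examples
#' estimate_users(33358 * 29500, 29500) # one year, 33,358 recipients
estimate_users <- function(annual_sales, avg_annual_cost, years = NULL) {
  if (!is.numeric(avg_annual_cost) || avg_annual_cost <= 0) {
    abort("`avg_annual_cost` must be positive.",
          class = "adrburden_domain_error")
  }
  if (any(annual_sales < 0)) {
    abort("`annual_sales` must be nonnegative.",
          class = "adrburden_domain_error")
  }
  years <- years %||% seq_along(annual_sales)
  new_users_estimate(
    tibble::tibble(year = years, users = round(annual_sales / avg_annual_cost)),
    source = list(annual_sales = annual_sales,
                  avg_annual_treatment_cost = avg_annual_cost)
  )
}

#' Construct a recipients estimate directly from user counts
#'
#' @param annual_users Recipients per year: a scalar (replicated across
#'   `years`) or a vector aligned with `years`.
#' @param years Calendar years covered.
#' @return A `users_estimate`.
#' @export
users_estimate <- function(annual_users, years) {
  if (length(annual_users) == 1) annual_users <- rep(annual_users, length(years))
  stopifnot(length(annual_users) == length(years), all(annual_users > 0))
  new_users_estimate(tibble::tibble(year = years, users = annual_users))
}

#' @export
print.users_estimate <- function(x, ...) {
  cat(sprintf("<users_estimate> mean %s recipients/year over %d year(s)\n",
              format(round(x$mean_annual_users), big.mark = ","),
              nrow(x$by_year)))
  invisible(x)
}

mean_annual_users <- function(users) {
  if (inherits(users, "users_estimate")) return(users$mean_annual_users)
  if (is.numeric(users) && length(users) == 1 && users > 0) return(users)
  abort("`users` must be a users_estimate or a positive scalar.",
        class = "adrburden_domain_error")
}

wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Post-market outcome rate per recipient with a 95% CI
#'
#' The point rate is `total events / (n_years x mean annual recipients)`.
#' Reported spontaneous-report rates vary between years far more than
#' binomial sampling alone predicts, so when per-year event counts are
#' supplied the default CI is a t-interval (df = years - 1) on the annual
#' rates; a Wilson binomial interval on the pooled counts is available and
#' is the fallback when only a total is given. The lower bound is truncated
#' at zero and the chosen method is recorded in the result.
#'
#' @param events Event (report) count: a per-year vector, or a scalar total.
#' @param users A [users_estimate()].
#' @param n_years Number of years pooled; defaults to the years in `users`.
#' @param conf_method `"annual_t"` or `"wilson"`.
#' @return A `rate_estimate` list: `rate`, `ci_low`, `ci_high`,
#'   `numerator`, `denominator`, `conf_method`.
#' @export
#' @examples
#' u <- users_estimate(33358, 2014:2018)
#' outcome_rate(rep(33013 / 5, 5), u) # 19.8% of recipients over 5 years
outcome_rate <- function(events, users, n_years = NULL,
                         conf_method = c("annual_t", "wilson")) {
  conf_method <- match.arg(conf_method)
  n_years <- n_years %||% nrow(users$by_year)
  if (n_years < 1) abort("`n_years` must be >= 1.", class = "adrburden_domain_error")
  if (any(events < 0)) abort("`events` must be nonnegative.",
                             class = "adrburden_domain_error")
  mu <- mean_annual_users(users)
  denom <- n_years * mu
  if (denom <= 0) abort("Zero recipient denominator.",
                        class = "adrburden_domain_error")
  total <- sum(events)
  rate <- total / denom
  per_year <- length(events) > 1
  if (per_year && length(events) != n_years) {
    abort("Per-year `events` must have one count per year.",
          class = "adrburden_domain_error")
  }
  if (conf_method == "annual_t" && per_year && n_years > 1) {
    r <- events / users$by_year$users
    half <- qt(0.975, df = n_years - 1) * sd(r) / sqrt(n_years)
    ci <- c(max(0, mean(r) - half), min(1, mean(r) + half))
  } else {
    conf_method <- "wilson"
    ci <- wilson_ci(total, denom)
  }
  structure(list(rate = rate, ci_low = ci[1], ci_high = ci[2],
                 numerator = total, denominator = denom,
                 conf_method = conf_method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.2f%% (95%% CI %.2f-%.2f%%; %s/%s; %s)\n",
              100 * x$rate, 100 * x$ci_low, 100 * x$ci_high,
              format(x$numerator, big.mark = ","),
              format(round(x$denominator), big.mark = ","), x$conf_method))
  invisible(x)
}

#' Post-market rate table: death, serious and all ADRs
#'
#' Mirrors the post-market columns of the reference analysis. The `death`
#' row counts death flags; the `serious` row adds the disability,
#' hospitalization and OMIC flag counts (death excluded by default, matching
#' the additive definition used in the reference analysis -- a report may
#' contribute several flags); the `all` row counts unique reports.
#'
#' @param reports A classified report tibble (with flags and dates).
#' @param users A [users_estimate()]; its years define the per-year counts.
#' @param include_death_in_serious Add death flags into the serious row?
#' @param conf_method Passed to [outcome_rate()].
#' @return A tibble with one row per outcome class and the rate estimate
#'   columns unpacked.
#' @export
rate_table <- function(reports, users, include_death_in_serious = FALSE,
                       conf_method = "annual_t") {
  yrs <- users$by_year$year
  yr <- as.integer(format(reports$initial_report_date, "%Y"))
  count_per_year <- function(keep) {
    vapply(yrs, function(y) sum(keep & yr == y, na.rm = TRUE), numeric(1))
  }
  serious_flags <- count_per_year(reports$flag_disability) +
    count_per_year(reports$flag_hospitalization) +
    count_per_year(reports$flag_omic) +
    if (include_death_in_serious) count_per_year(reports$flag_death) else 0
  rows <- list(
    death = count_per_year(reports$flag_death),
    serious = serious_flags,
    all = count_per_year(rep(TRUE, nrow(reports)))
  )
  purrr::imap_dfr(rows, function(ev, nm) {
    r <- outcome_rate(ev, users, conf_method = conf_method)
    tibble::tibble(outcome = nm, rate = r$rate, ci_low = r$ci_low,
                   ci_high = r$ci_high, numerator = r$numerator,
                   denominator = r$denominator, conf_method = r$conf_method)
  })
}
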