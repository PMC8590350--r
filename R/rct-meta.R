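# Random-effects pooling of trial adverse-event proportions. The
# DerSimonian-Laird estimator is implemented here directly (on untransformed
# proportions) rather than delegated to a meta-analysis package: pooled
# rates reported as "not significantly different from zero" only arise on
# the raw-proportion scale, and the estimator is the quantity under test.

#' Read trial-arm summaries from CSV
#'
#' Expects columns `trial_id`, `n` (participants), `all_ae`, `serious`,
#' `deaths`. Restricting arms to monotherapy with the study drug is the
#' caller's responsibility; the file format cannot express it.
#'
#' @param path CSV file path.
#' @return A tibble of trial arms, validated (counts within `[0, n]`).
#' @export
read_trial_arms <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Trial-arm file not found: %s", path),
          class = "adrburden_format_error")
  }
  arms <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "n", "all_ae", "serious", "deaths")
  missing <- setdiff(need, names(arms))
  if (length(missing)) {
    abort(sprintf("Trial-arm file is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "adrburden_format_error")
  }
  for (col in c("all_ae", "serious", "deaths")) {
    bad <- arms[[col]] < 0 | arms[[col]] > arms$n
    if (any(bad)) {
      abort(sprintf("Column `%s` has counts outside [0, n] in row(s) %s.",
                    col, paste(which(bad), collapse = ", ")),
            class = "adrburden_format_error")
    }
  }
  if (any(arms$n < 1)) {
    abort("All arms need `n` >= 1.", class = "adrburden_format_error")
  }
  arms[need]
}

#' Per-arm event proportion and sampling variance
#'
#' `p = x/n`, `var = p(1-p)/n`. Arms with zero or all events get the
#' standard continuity correction (0.5 added to the event count, 1 to the
#' denominator) before both quantities are computed, keeping the variance
#' finite and the adjustment symmetric at `x = n`.
#'
#' @param arms Trial-arm tibble (see [read_trial_arms()]).
#' @param event_field `"all_ae"`, `"serious"` or `"deaths"`.
#' @return A tibble with columns `p` and `var`, one row per arm.
#' @export
#' @examples
#' arm_proportion(data.frame(n = 50, deaths = 0), "deaths") # p = 0.5/51
arm_proportion <- function(arms, event_field) {
  x <- arms[[event_field]]
  n <- arms$n
  if (is.null(x)) {
    abort(sprintf("No column `%s` in `arms`.", event_field),
          class = "adrburden_domain_error")
  }
  if (any(n <= 0)) abort("Arm sizes must be positive.",
                         class = "adrburden_domain_error")
  adj <- x == 0 | x == n
  x2 <- ifelse(adj, x + 0.5, x)
  n2 <- ifelse(adj, n + 1, n)
  p <- x2 / n2
  tibble::tibble(p = p, var = p * (1 - p) / n2)
}

#' DerSimonian-Laird random-effects pooled proportion
#'
#' Moment-based random-effects meta-analysis on untransformed proportions:
#' fixed-effect weights `w = 1/var` give the heterogeneity statistic
#' `Q = sum w (p - p_FE)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(var + tau2)` give the pooled estimate and its 95% CI
#' (`+/- 1.96 SE`). The estimate is flagged significant when the CI
#' excludes zero.
#'
#' @inheritParams arm_proportion
#' @return A `meta_result`: `pooled`, `ci_low`, `ci_high` (reported
#'   truncated to `[0, 1]`), `se`, `tau2`, `Q`, `I2`, `k`, `significant`.
#' @export
dl_pool <- function(arms, event_field) {
  pv <- arm_proportion(arms, event_field)
  k <- nrow(pv)
  if (k == 0) abort("Need at least one arm.", class = "adrburden_domain_error")
  w <- 1 / pv$var
  p_fe <- sum(w * pv$p) / sum(w)
  Q <- sum(w * (pv$p - p_fe)^2)
  tau2 <- if (k == 1) 0 else {
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  wr <- 1 / (pv$var + tau2)
  pooled <- sum(wr * pv$p) / sum(wr)
  se <- sqrt(1 / sum(wr))
  ci <- pooled + c(-1, 1) * 1.96 * se
  I2 <- if (k == 1 || Q <= 0) 0 else max(0, (Q - (k - 1)) / Q)
  structure(list(pooled = pooled, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
                 se = se, tau2 = tau2, Q = Q, I2 = I2, k = k,
                 significant = ci[1] > 0),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> pooled %.3f%% (95%% CI %.3f-%.3f%%)%s\n",
              100 * x$pooled, 100 * x$ci_low, 100 * x$ci_high,
              if (x$significant) "" else " [NS]"))
  cat(sprintf("  k = %d, tau2 = %.3g, Q = %.3g, I2 = %.1f%%\n",
              x$k, x$tau2, x$Q, 100 * x$I2))
  invisible(x)
}

#' Fold difference between a post-market rate and a pooled RCT rate
#'
#' Ratio of the point estimates, with a qualitative flag when the pooled
#' RCT estimate is not significantly different from zero (a ratio against a
#' statistically-zero rate is reported but should be read as a lower
#' bound's inverse; when the pooled rate itself is zero the ratio is
#' undefined).
#'
#' @param post_market A `rate_estimate` (or a bare proportion).
#' @param rct A `meta_result` from [dl_pool()].
#' @return List with `fold` (NA when the RCT rate is zero),
#'   `rct_not_significant`, and the two point estimates.
#' @export
compare_rates <- function(post_market, rct) {
  post <- if (inherits(post_market, "rate_estimate")) post_market$rate else post_market
  stopifnot(inherits(rct, "meta_result"))
  fold <- if (rct$pooled > 0) post / rct$pooled else NA_real_
  list(fold = fold, rct_not_significant = !rct$significant,
       post_rate = post, rct_rate = rct$pooled)
}
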