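#' Round half away from zero
#'
#' Summary tables round half away from zero at the printed precision
#' (unlike base [round()], which rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # snap away float representation error before taking the half-step
  z <- round(x * scale, 9)
  sign(z) * floor(abs(z) + 0.5) / scale
}

#' Relative change in percent
#'
#' @param start Positive baseline value(s).
#' @param end End value(s).
#' @return `(end / start - 1) * 100`.
#' @export
relative_change <- function(start, end) {
  if (any(!is.finite(start)) || any(start <= 0)) {
    stop("`start` must be finite and > 0", call. = FALSE)
  }
  (end / start - 1) * 100
}

#' Build the scenario summary table
#'
#' One row per (sex, scenario) plus a pooled `total` block, in the layout
#' of a published projection summary: crude prevalence (%) and case
#' counts (millions) in the start and end years, and their relative
#' changes (%).  Relative changes are computed from the unrounded start
#' and end values and only then rounded to integer percent; prevalence
#' and cases are printed to one decimal.  The pooled `total` prevalence
#' is count-pooled (pooled cases over pooled population), not an average
#' of the sex-specific prevalences.
#'
#' @param results Named list of `projection_result` objects (names are
#'   scenario labels; unnamed lists use each result's own scenario).
#' @param start_year,end_year Comparison years (defaults 2015 and 2040).
#' @return Data frame with columns `sex`, `scenario`,
#'   `prevalence_start`, `cases_start`, `prevalence_end`, `cases_end`,
#'   `change_prevalence`, `change_cases`.
#' @export
make_summary_table <- function(results, start_year = 2015, end_year = 2040) {
  if (inherits(results, "projection_result")) results <- list(results)
  labels <- names(results)
  if (is.null(labels)) {
    labels <- vapply(results, function(r) r$scenario, character(1))
    names(results) <- labels
  }
  rows <- list()
  for (s in c("male", "female", "total")) {
    for (sc in labels) {
      tot <- results[[sc]]$totals
      a <- tot[tot$sex == s & tot$year == start_year, ]
      b <- tot[tot$sex == s & tot$year == end_year, ]
      if (nrow(a) != 1L || nrow(b) != 1L) {
        stop(sprintf("scenario '%s' lacks totals for sex '%s' in %g/%g",
                     sc, s, start_year, end_year), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, scenario = sc,
        prevalence_start = round_half_up(100 * a$prevalence, 1),
        cases_start = round_half_up(a$cases / 1e6, 1),
        prevalence_end = round_half_up(100 * b$prevalence, 1),
        cases_end = round_half_up(b$cases / 1e6, 1),
        change_prevalence = round_half_up(
          relative_change(a$prevalence, b$prevalence)),
        change_cases = round_half_up(relative_change(a$cases, b$cases)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference summary table of a published national projection
#'
#' Printed summary values (crude prevalence in percent, case counts in
#' millions, and relative changes 2015 to 2040 in percent) of a published
#' projection of diagnosed type 2 diabetes among adults in Germany, by
#' sex and scenario.  Used to validate the reporting arithmetic: for the
#' cells whose printed relative change is self-consistent with the
#' printed start/end values, [relative_change()] plus
#' [round_half_up()] must reproduce the printed change exactly.
#'
#' @return Data frame in the layout of [make_summary_table()].
#' @export
reference_summary_table <- function() {
  scen <- scenario_names()[c(1, 2, 3, 4, 5, 6)]
  df <- rbind(
    data.frame(sex = "male", scenario = scen,
               prevalence_start = 10.5, cases_start = 3.5,
               prevalence_end = c(12.1, 16.6, 17.9, 19.4, 20.6, 21.1),
               cases_end = c(4.1, 5.7, 6.2, 6.7, 7.1, 7.2),
               change_prevalence = c(14, 58, 70, 84, 95, 100),
               change_cases = c(18, 62, 75, 90, 101, 106)),
    data.frame(sex = "female", scenario = scen,
               prevalence_start = 9.5, cases_start = 3.3,
               prevalence_end = c(10.8, 14.5, 15.9, 17.5, 18.7, 19.2),
               cases_end = c(3.9, 5.2, 5.7, 6.3, 6.8, 7.0),
               change_prevalence = c(14, 53, 67, 84, 97, 103),
               change_cases = c(18, 57, 73, 90, 104, 109)),
    data.frame(sex = "total", scenario = scen,
               prevalence_start = 10.0, cases_start = 6.8,
               prevalence_end = c(11.4, 15.5, 16.9, 18.4, 19.6, 20.1),
               cases_end = c(8.1, 10.9, 11.9, 13.0, 13.8, 14.2),
               change_prevalence = c(14, 55, 69, 84, 96, 101),
               change_cases = c(18, 60, 74, 90, 103, 108))
  )
  rownames(df) <- NULL
  df
}

#' Check the internal arithmetic of a printed summary table
#'
#' Recomputes each relative-change cell from the printed start/end values
#' (via [relative_change()] and [round_half_up()]) and reports agreement
#' with the printed change.  Printed tables round hidden digits, so a
#' minority of cells may legitimately disagree by one point; the
#' self-consistent cells must be reproduced exactly.
#'
#' @param table Data frame in the layout of [make_summary_table()].
#' @return The table with extra columns `recomputed_change_prevalence`,
#'   `recomputed_change_cases`, `consistent_prevalence`,
#'   `consistent_cases`.
#' @export
check_summary_arithmetic <- function(table) {
  table$recomputed_change_prevalence <- round_half_up(
    relative_change(table$prevalence_start, table$prevalence_end))
  table$recomputed_change_cases <- round_half_up(
    relative_change(table$cases_start, table$cases_end))
  table$consistent_prevalence <-
    table$recomputed_change_prevalence == table$change_prevalence
  table$consistent_cases <-
    table$recomputed_change_cases == table$change_cases
  table
}

#' Observed versus fitted grouped incidence
#'
#' Convenience table behind incidence-trend figures: the grouped
#' estimates next to the trend-model fit at the groups' representative
#' ages.
#'
#' @param model An [fit_incidence_trend()] result.
#' @param estimates The estimate table used for fitting.
#' @return The estimates with an extra `fitted` column (per person-year).
#' @export
incidence_fit_table <- function(model, estimates) {
  est <- estimates[!grepl("^<", as.character(estimates$age_group)), , drop = FALSE]
  mid <- midpoint_of(est$age_group, open_age = model$open_age)
  est$fitted <- predict_incidence(model, est$sex, mid, est$year)
  est
}

#' Horizon-year age profile of projected prevalence, by scenario
#'
#' @param results Named list of `projection_result` objects.
#' @param year Year to extract (default: last common year).
#' @return Long data frame: `scenario`, `sex`, `age`, `prevalence`.
#' @export
age_prevalence_at <- function(results, year = NULL) {
  rows <- list()
  for (sc in names(results)) {
    for (s in c("male", "female")) {
      surf <- results[[sc]]$prevalence[[s]]
      y <- if (is.null(year)) max(surf$years) else year
      j <- match(y, surf$years)
      if (is.na(j)) stop(sprintf("year %g not in scenario '%s'", y, sc),
                         call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, sex = s, age = surf$ages,
        prevalence = surf$values[, j], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Projected total case counts by scenario and year
#'
#' @param results Named list of `projection_result` objects.
#' @return Long data frame: `scenario`, `year`, `cases` (persons, pooled
#'   over sexes).
#' @export
cases_by_scenario <- function(results) {
  rows <- list()
  for (sc in names(results)) {
    tot <- results[[sc]]$totals
    tot <- tot[tot$sex == "total", ]
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, year = tot$year, cases = tot$cases,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
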