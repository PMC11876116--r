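#' Read a typed demographic input table
#'
#' All inputs are comma-separated UTF-8 text with a header row.  Column
#' contracts by `kind`:
#' \describe{
#'   \item{incidence_estimates}{`sex`, `age_group` (`"lo-hi"`/`"lo+"`
#'     tokens; a leading `"<hi"` group is tolerated and later dropped by
#'     the adult-only trend model), `year`, `rate`.}
#'   \item{mortality}{`sex`, `age`, `year`, `rate`.}
#'   \item{prevalence}{`sex`, `age`, `year`, `prevalence`.}
#'   \item{mrr}{`sex`, `age`, `mrr` (baseline year profile).}
#'   \item{population}{`sex`, `age`, `year`, `count`.}
#' }
#'
#' @param path File path.
#' @param kind One of the five input kinds above.
#' @param rate_unit `"per1"` (default) or `"per1000"`; per-1000
#'   person-year rates are rescaled to per-1 on read.  Only meaningful
#'   for the rate kinds (`incidence_estimates`, `mortality`).
#' @return A validated data frame in per-1 units.
#' @export
read_rate_table <- function(path,
                            kind = c("incidence_estimates", "mortality",
                                     "prevalence", "mrr", "population"),
                            rate_unit = c("per1", "per1000")) {
  kind <- match.arg(kind)
  rate_unit <- match.arg(rate_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  contract <- switch(kind,
    incidence_estimates = list(cols = c("sex", "age_group", "year", "rate"),
                               value = "rate", key = c("sex", "age_group", "year")),
    mortality = list(cols = c("sex", "age", "year", "rate"),
                     value = "rate", key = c("sex", "age", "year")),
    prevalence = list(cols = c("sex", "age", "year", "prevalence"),
                      value = "prevalence", key = c("sex", "age", "year")),
    mrr = list(cols = c("sex", "age", "mrr"),
               value = "mrr", key = c("sex", "age")),
    population = list(cols = c("sex", "age", "year", "count"),
                      value = "count", key = c("sex", "age", "year"))
  )
  missing_cols <- setdiff(contract$cols, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s table '%s' lacks column(s): %s", kind, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[contract$cols]
  bad_sex <- !df$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop(sprintf("invalid sex value(s) in rows %s of '%s'",
                 paste(utils::head(which(bad_sex), 5L), collapse = ", "), path),
         call. = FALSE)
  }
  if (kind == "incidence_estimates") {
    ok <- grepl("^[0-9]+-[0-9]+$|^[0-9]+\\+$|^<[0-9]+$", df$age_group)
    if (any(!ok)) {
      stop(sprintf("unparseable age group(s) in rows %s of '%s': %s",
                   paste(utils::head(which(!ok), 5L), collapse = ", "), path,
                   paste(unique(df$age_group[!ok]), collapse = ", ")),
           call. = FALSE)
    }
  }
  v <- df[[contract$value]]
  if (any(!is.finite(v))) {
    stop(sprintf("non-finite %s value(s) in rows %s of '%s'", contract$value,
                 paste(utils::head(which(!is.finite(v)), 5L), collapse = ", "),
                 path), call. = FALSE)
  }
  lower <- if (kind == "mrr") 1 else 0
  if (any(v < lower)) {
    stop(sprintf("%s value(s) below %g in rows %s of '%s'", contract$value,
                 lower, paste(utils::head(which(v < lower), 5L), collapse = ", "),
                 path), call. = FALSE)
  }
  if (kind == "prevalence" && any(v > 1)) {
    stop(sprintf("prevalence value(s) above 1 in rows %s of '%s'",
                 paste(utils::head(which(v > 1), 5L), collapse = ", "), path),
         call. = FALSE)
  }
  dup <- duplicated(df[contract$key])
  if (any(dup)) {
    stop(sprintf("duplicate key(s) (%s) in rows %s of '%s'",
                 paste(contract$key, collapse = ", "),
                 paste(utils::head(which(dup), 5L), collapse = ", "), path),
         call. = FALSE)
  }
  if (rate_unit == "per1000") {
    if (!kind %in% c("incidence_estimates", "mortality")) {
      stop("`rate_unit = 'per1000'` only applies to rate tables ",
           "(incidence_estimates, mortality)", call. = FALSE)
    }
    df[[contract$value]] <- df[[contract$value]] / 1000
  }
  df
}

#' Write a demographic table as CSV
#'
#' @param df Data frame to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(df, path) {
  # doubles are written with 17 significant digits so that a
  # write-then-read round trip reproduces them bit-exactly
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a per-sex surface from a long-format table
#'
#' @param table Long-format data frame with columns `sex`, `age`, `year`
#'   and a value column (`rate`, `prevalence`, or as named in `value_col`).
#' @param sex Which sex to extract.
#' @param value_col Name of the value column; guessed if `NULL`.
#' @param kind `"rate"` or `"prevalence"` surface to construct.
#' @return A [rate_surface()] or [prevalence_surface()].
#' @export
surface_from_table <- function(table, sex, value_col = NULL,
                               kind = c("rate", "prevalence")) {
  kind <- match.arg(kind)
  if (is.null(value_col)) {
    value_col <- intersect(c("rate", "prevalence", "value"), names(table))[1L]
    if (is.na(value_col)) stop("cannot identify the value column", call. = FALSE)
  }
  d <- table[table$sex == sex, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for sex '", sex, "'", call. = FALSE)
  ages <- sort(unique(d$age))
  years <- sort(unique(d$year))
  if (nrow(d) != length(ages) * length(years)) {
    stop("table is not a complete age x year grid for sex '", sex, "'",
         call. = FALSE)
  }
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(ages, years))
  m[cbind(match(d$age, ages), match(d$year, years))] <- d[[value_col]]
  ctor <- if (kind == "prevalence") prevalence_surface else rate_surface
  ctor(sex, ages, years, m)
}

# Map the population of one sex and year onto an age grid: single ages
# above the top grid node (open-ended top group) are pooled into the top
# node; ages below the minimum are dropped (not modeled).
population_on_grid <- function(population, sex, year, ages) {
  d <- population[population$sex == sex & population$year == year, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("population has no rows for sex '%s', year %g", sex, year),
         call. = FALSE)
  }
  d <- d[d$age >= ages[1L], , drop = FALSE]
  a <- pmin(d$age, ages[length(ages)])
  out <- numeric(length(ages))
  agg <- tapply(d$count, factor(a, levels = ages), sum, default = 0)
  out[] <- as.numeric(agg)
  out
}

#' Convert a prevalence surface to case counts for one year
#'
#' `count(a) = p(a) * N(a)`, with the adult total as the sum over the age
#' grid.  Population ages above the top grid node are pooled into the top
#' node (open-ended top age group).
#'
#' @param prevalence A [prevalence_surface()].
#' @param population Data frame with columns `sex`, `age`, `year`, `count`.
#' @param year Calendar year (must be present in both inputs).
#' @return A list with `age`, `prevalence`, `cases` (age-specific) and
#'   `total_cases`, `total_population`.
#' @export
counts_from_prevalence <- function(prevalence, population, year) {
  j <- match(year, prevalence$years)
  if (is.na(j)) {
    stop(sprintf("year %g not covered by the prevalence surface", year),
         call. = FALSE)
  }
  N <- population_on_grid(population, prevalence$sex, year, prevalence$ages)
  p <- prevalence$values[, j]
  list(age = prevalence$ages, prevalence = p, cases = p * N,
       total_cases = sum(p * N), total_population = sum(N))
}

#' Population-weighted (crude) prevalence among adults
#'
#' @inheritParams counts_from_prevalence
#' @return The crude prevalence
#'   \eqn{\sum_a p(a) N(a) / \sum_a N(a)} over the surface's age grid.
#' @export
overall_prevalence <- function(prevalence, population, year) {
  cc <- counts_from_prevalence(prevalence, population, year)
  if (cc$total_population <= 0) {
    stop("total population is zero; crude prevalence undefined", call. = FALSE)
  }
  cc$total_cases / cc$total_population
}

#' Constant-prevalence counterfactual projection
#'
#' Freezes the age- and sex-specific prevalence at a reference profile
#' and lets only demographic change move the counts.
#'
#' @param reference Named list (`male`, `female`) of prevalence profiles
#'   over `ages` (numeric vectors, or functions of age).
#' @param population Data frame with columns `sex`, `age`, `year`, `count`.
#' @param years Years to report.
#' @param ages Age grid of the reference profiles.
#' @param scenario Scenario label stored in the result.
#' @return A `projection_result` (see [run_scenario()]).
#' @export
constant_prevalence_projection <- function(reference, population, years,
                                           ages = 18:100,
                                           scenario = "constant_prevalence") {
  sexes <- c("male", "female")
  prevalence <- lapply(stats::setNames(sexes, sexes), function(s) {
    prof <- reference[[s]]
    if (is.null(prof)) {
      stop("`reference` must contain entries 'male' and 'female'",
           call. = FALSE)
    }
    if (is.function(prof)) prof <- prof(ages)
    if (length(prof) != length(ages)) {
      stop("reference profile must cover the age grid", call. = FALSE)
    }
    prevalence_surface(s, ages, years,
                       matrix(prof, nrow = length(ages), ncol = length(years)))
  })
  build_projection_result(scenario, prevalence, population, years)
}
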