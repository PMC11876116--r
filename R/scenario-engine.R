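#' Projection scenario names
#'
#' Six scenarios: a counterfactual that freezes the age-specific
#' prevalence at its first reported year, a constant-incidence scenario
#' that freezes incidence at the last observed year (2021), and four
#' scenarios that extrapolate the fitted incidence trend until 2025,
#' 2030, 2035 or 2040 and hold it constant thereafter.
#'
#' @return Character vector of the six scenario names.
#' @export
scenario_names <- function() {
  c("constant_prevalence", "constant_incidence",
    "trend_until_2025", "trend_until_2030",
    "trend_until_2035", "trend_until_2040")
}

#' Scenario specification
#'
#' @param name One of [scenario_names()].
#' @param base_year First year of the projection (default 2010; the
#'   starting prevalence refers to this year).
#' @param report_start First reported year (default 2015).  Incidence for
#'   years before `report_start` is taken as the `report_start`
#'   prediction.
#' @param horizon Last projected year (default 2040).
#' @param observed_end Last year covered by the observed incidence
#'   estimates (default 2021); the constant-incidence scenario freezes
#'   incidence at this year.
#' @return An object of class `scenario_spec` with the implied
#'   `trend_end_year` (`NA` for `constant_prevalence`).
#' @export
scenario_spec <- function(name, base_year = 2010, report_start = 2015,
                          horizon = 2040, observed_end = 2021) {
  name <- match.arg(name, scenario_names())
  trend_end <- switch(name,
    constant_prevalence = NA_real_,
    constant_incidence = observed_end,
    as.numeric(sub("^trend_until_", "", name))
  )
  if (!is.na(trend_end) && (trend_end < observed_end || trend_end > horizon)) {
    stop(sprintf("trend_end_year %g outside [%g, %g]", trend_end,
                 observed_end, horizon), call. = FALSE)
  }
  structure(list(name = name, trend_end_year = trend_end,
                 base_year = base_year, report_start = report_start,
                 horizon = horizon, observed_end = observed_end),
            class = "scenario_spec")
}

#' Build the scenario incidence surface from a fitted trend model
#'
#' For years before `report_start` the `report_start` prediction is used;
#' between `report_start` and the scenario's `trend_end_year` the fitted
#' trend (including its natural linear extrapolation beyond the observed
#' years) applies; after `trend_end_year` the incidence is frozen per
#' (sex, age) cell at its `trend_end_year` value.
#'
#' @param model An [fit_incidence_trend()] result.
#' @param scenario A [scenario_spec()] (not `constant_prevalence`).
#' @param sex `"male"` or `"female"`.
#' @param ages,years Grids for the returned surface.
#' @return A [rate_surface()].
#' @export
build_incidence_surface <- function(model, scenario, sex,
                                    ages = 18:100,
                                    years = scenario$base_year:scenario$horizon) {
  if (!inherits(scenario, "scenario_spec")) {
    stop("`scenario` must be a scenario_spec", call. = FALSE)
  }
  if (scenario$name == "constant_prevalence") {
    stop("the constant_prevalence scenario has no incidence surface; ",
         "it bypasses the projection model", call. = FALSE)
  }
  rate_surface_from_function(
    function(age, year) {
      y_eff <- pmin(pmax(year, scenario$report_start), scenario$trend_end_year)
      predict_incidence(model, sex, age, y_eff)
    },
    sex = sex, ages = ages, years = years
  )
}

#' Run one projection scenario
#'
#' Orchestrates a full scenario: builds the per-sex scenario incidence
#' surfaces, integrates the prevalence equation from the base-year
#' starting profile to the horizon, and converts prevalence to counts
#' with the population projection.  The `constant_prevalence` scenario
#' bypasses the projection model: the age-specific prevalence at
#' `report_start` (obtained from the shared pre-`observed_end` incidence
#' segment, identical across scenarios) is held fixed and only
#' demographic change moves the counts.
#'
#' @param scenario A [scenario_spec()] or scenario name.
#' @param model An [fit_incidence_trend()] result.
#' @param baseline_prevalence Named list (`male`, `female`) of numeric
#'   prevalence profiles over `ages` in the base year.
#' @param mortality Named list (`male`, `female`) of [rate_surface()]s.
#' @param mrr Named list (`male`, `female`) of [mrr_schedule()]s.
#' @param population Data frame with columns `sex`, `age`, `year`, `count`.
#' @param ages,years Projection grids (unit-spaced).
#' @param step RK4 integration step in years.
#' @return A `projection_result`: list with `scenario`, per-sex
#'   `prevalence` surfaces (reported years), `counts` (long data frame)
#'   and `totals` (adult totals per sex and pooled, per year).
#' @export
run_scenario <- function(scenario, model, baseline_prevalence, mortality, mrr,
                         population, ages = 18:100, years = NULL, step = 0.1) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.null(years)) years <- scenario$base_year:scenario$horizon
  sexes <- c("male", "female")
  for (s in sexes) {
    if (is.null(baseline_prevalence[[s]]) || is.null(mortality[[s]]) ||
        is.null(mrr[[s]])) {
      stop("baseline_prevalence, mortality and mrr must be named lists ",
           "with 'male' and 'female' entries", call. = FALSE)
    }
  }
  report_years <- years[years >= scenario$report_start]

  if (scenario$name == "constant_prevalence") {
    # shared 2010-2015 segment: all PDE scenarios coincide there, so use
    # the constant-incidence surface to carry the starting profile to the
    # first reported year
    carrier <- scenario_spec("constant_incidence",
                             base_year = scenario$base_year,
                             report_start = scenario$report_start,
                             horizon = scenario$horizon,
                             observed_end = scenario$observed_end)
    pre_years <- scenario$base_year:scenario$report_start
    reference <- lapply(stats::setNames(sexes, sexes), function(s) {
      inc <- build_incidence_surface(model, carrier, s, ages, pre_years)
      surf <- project_prevalence_surface(baseline_prevalence[[s]],
                                         incidence = inc,
                                         mortality = mortality[[s]],
                                         mrr = mrr[[s]],
                                         ages = ages, years = pre_years,
                                         step = step)
      surf$values[, ncol(surf$values)]
    })
    return(constant_prevalence_projection(reference, population,
                                          years = report_years, ages = ages,
                                          scenario = scenario$name))
  }

  prevalence <- lapply(stats::setNames(sexes, sexes), function(s) {
    inc <- build_incidence_surface(model, scenario, s, ages, years)
    surf <- project_prevalence_surface(baseline_prevalence[[s]],
                                       incidence = inc,
                                       mortality = mortality[[s]],
                                       mrr = mrr[[s]],
                                       ages = ages, years = years,
                                       step = step)
    keep <- surf$years >= scenario$report_start
    prevalence_surface(s, surf$ages, surf$years[keep],
                       surf$values[, keep, drop = FALSE])
  })
  build_projection_result(scenario$name, prevalence, population, report_years)
}

# Assemble counts and totals from per-sex prevalence surfaces.
build_projection_result <- function(name, prevalence, population, years) {
  counts <- list()
  totals <- list()
  for (s in names(prevalence)) {
    surf <- prevalence[[s]]
    for (y in years) {
      cc <- counts_from_prevalence(surf, population, y)
      counts[[length(counts) + 1L]] <-
        data.frame(sex = s, age = cc$age, year = y, cases = cc$cases)
      totals[[length(totals) + 1L]] <-
        data.frame(sex = s, year = y,
                   prevalence = cc$total_cases / cc$total_population,
                   cases = cc$total_cases,
                   population = cc$total_population)
    }
  }
  totals <- do.call(rbind, totals)
  pooled <- do.call(rbind, lapply(split(totals, totals$year), function(d) {
    data.frame(sex = "total", year = d$year[1L],
               prevalence = sum(d$cases) / sum(d$population),
               cases = sum(d$cases), population = sum(d$population))
  }))
  totals <- rbind(totals, pooled)
  rownames(totals) <- NULL
  structure(list(scenario = name, prevalence = prevalence,
                 counts = do.call(rbind, counts), totals = totals),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  yrs <- range(x$totals$year)
  cat(sprintf("<projection result: scenario '%s', years %g-%g>\n",
              x$scenario, yrs[1L], yrs[2L]))
  tot <- x$totals[x$totals$sex == "total" & x$totals$year %in% yrs, ]
  for (k in seq_len(nrow(tot))) {
    cat(sprintf("  %g: prevalence %.1f%%, cases %.2f million\n",
                tot$year[k], 100 * tot$prevalence[k], tot$cases[k] / 1e6))
  }
  invisible(x)
}
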