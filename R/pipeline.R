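#' Load a full projection input set from a directory
#'
#' Expects the file layout written by [write_synthetic_inputs()] (or any
#' equivalently formatted real inputs): `config.yaml`,
#' `incidence_estimates.csv`, `prevalence.csv`, `mortality.csv`,
#' `mrr.csv`, `population.csv`.
#'
#' @param dir Input directory.
#' @return A list with `config`, `estimates` (per-1 units), `baseline`
#'   (named list of base-year prevalence profiles), `mortality` (named
#'   list of [rate_surface()]s), `mrr` (named list of [mrr_schedule()]s),
#'   `population` (data frame) and `ages`/`years` grids.
#' @export
load_inputs <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop("missing config.yaml in ", dir, call. = FALSE)
  config <- yaml::read_yaml(cfg_path)
  units <- config$rate_units
  unit_of <- function(kind) {
    u <- units[[kind]]
    if (is.null(u)) "per1" else u
  }
  estimates <- read_rate_table(file.path(dir, "incidence_estimates.csv"),
                               "incidence_estimates",
                               rate_unit = unit_of("incidence_estimates"))
  prev_tab <- read_rate_table(file.path(dir, "prevalence.csv"), "prevalence")
  mort_tab <- read_rate_table(file.path(dir, "mortality.csv"), "mortality",
                              rate_unit = unit_of("mortality"))
  mrr_tab <- read_rate_table(file.path(dir, "mrr.csv"), "mrr")
  population <- read_rate_table(file.path(dir, "population.csv"), "population")
  ages <- config$min_age:config$max_age
  years <- config$base_year:config$horizon
  sexes <- stats::setNames(c("male", "female"), c("male", "female"))
  baseline <- lapply(sexes, function(s) {
    d <- prev_tab[prev_tab$sex == s & prev_tab$year == config$base_year, ]
    d <- d[order(d$age), ]
    if (!identical(as.numeric(d$age), as.numeric(ages))) {
      stop("baseline prevalence does not cover the age grid for sex ", s,
           call. = FALSE)
    }
    d$prevalence
  })
  mortality <- lapply(sexes, function(s) surface_from_table(mort_tab, s))
  mrr <- lapply(sexes, function(s) {
    d <- mrr_tab[mrr_tab$sex == s, ]
    d <- d[order(d$age), ]
    mrr_schedule(s, base_year = config$base_year, ages = d$age,
                 base_mrr = d$mrr,
                 annual_factor = config$mrr_annual_factor)
  })
  list(config = config, estimates = estimates, baseline = baseline,
       mortality = mortality, mrr = mrr, population = population,
       ages = ages, years = years)
}

#' Project a set of scenarios from loaded inputs
#'
#' @param inputs A [load_inputs()] result.
#' @param model An [fit_incidence_trend()] result.
#' @param scenarios Scenario names (default: all six).
#' @param step RK4 integration step in years (default from the config).
#' @return Named list of `projection_result` objects.
#' @export
project_scenarios <- function(inputs, model, scenarios = scenario_names(),
                              step = NULL) {
  cfg <- inputs$config
  if (is.null(step)) step <- if (is.null(cfg$step)) 0.1 else cfg$step
  out <- lapply(stats::setNames(scenarios, scenarios), function(sc) {
    spec <- scenario_spec(sc, base_year = cfg$base_year,
                          report_start = cfg$report_start,
                          horizon = cfg$horizon,
                          observed_end = cfg$observed_end)
    run_scenario(spec, model, inputs$baseline, inputs$mortality, inputs$mrr,
                 inputs$population, ages = inputs$ages, years = inputs$years,
                 step = step)
  })
  out
}
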