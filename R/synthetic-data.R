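#' Standard adult age groups of the grouped incidence estimates
#'
#' @return Character vector of the five adult group tokens.
#' @export
standard_age_groups <- function() {
  c("18-34", "35-49", "50-64", "65-79", "80+")
}

# Admissible default parameters of the synthetic ground truth.  Rates are
# per person-year; anchor incidence values give an adult prevalence near
# 10% in 2015 at the default mortality/MRR, mirroring the regime of the
# German type 2 diabetes inputs.  Jitters are applied on the log scale
# (multiplicative), so random draws stay positive and in-span.
default_truth_params <- function() {
  list(
    anchor_ages = c(26, 42, 57, 72, 85),
    anchor_rates = list(male = c(0.9, 3.4, 8.2, 12, 11) / 1000,
                        female = c(0.75, 2.6, 6.7, 10.5, 10.5) / 1000),
    gamma = list(male = 0.015, female = 0.010),  # log-incidence trend / year
    anchor_jitter_sd = 0.08,                     # log-scale sd of anchor jitter
    gamma_jitter_sd = 0.25,                      # log-scale sd of trend jitter
    gompertz_a = list(male = 4.2e-05, female = 3.0e-05),
    gompertz_b = 0.092,
    mortality_improvement = 0.99,                # per-year factor
    mortality_jitter_sd = 0.05,
    mrr_ages = c(30, 60, 90),
    mrr_values = c(3.0, 2.0, 1.3),
    mrr_annual_factor = 0.98,
    mrr_jitter_sd = 0.05,                        # on (MRR - 1), log scale
    p18 = 0.004,                                 # prevalence of entering cohorts
    pop_anchor_ages = c(18, 25, 35, 45, 55, 65, 75, 85, 95, 100),
    pop_anchor_counts = c(950, 1000, 970, 1350, 1200, 950, 1050, 450, 70, 5) * 1000,
    pop_aging_drift = 0.4,                       # years of pyramid shift per year
    pop_growth = 1.0,                            # total-size factor per year
    base_year = 2010,
    trend_ref_year = 2015
  )
}

check_truth_params <- function(p) {
  must_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("inadmissible parameter `", nm, "`: must be finite and > 0",
           call. = FALSE)
    }
  }
  must_pos(unlist(p$anchor_rates), "anchor_rates")
  must_pos(unlist(p$gompertz_a), "gompertz_a")
  must_pos(p$gompertz_b, "gompertz_b")
  must_pos(p$pop_anchor_counts, "pop_anchor_counts")
  if (any(p$mrr_values < 1)) {
    stop("inadmissible parameter `mrr_values`: must be >= 1", call. = FALSE)
  }
  if (p$mrr_annual_factor <= 0 || p$mrr_annual_factor > 1) {
    stop("inadmissible parameter `mrr_annual_factor`: must be in (0, 1]",
         call. = FALSE)
  }
  if (p$mortality_improvement <= 0 || p$mortality_improvement > 1.05) {
    stop("inadmissible parameter `mortality_improvement`", call. = FALSE)
  }
  if (p$p18 < 0 || p$p18 > 0.05) {
    stop("inadmissible parameter `p18`: must be in [0, 0.05]", call. = FALSE)
  }
  if (length(p$anchor_ages) != length(p$anchor_rates$male) ||
      length(p$anchor_ages) != length(p$anchor_rates$female)) {
    stop("`anchor_rates` must match `anchor_ages` in length", call. = FALSE)
  }
  invisible(NULL)
}

# Run code with a temporary RNG state seeded by `seed` (NULL = leave the
# global stream untouched).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic ground truth
#'
#' Builds deterministic, everywhere-evaluable laws for incidence,
#' general-population mortality, the mortality rate ratio and the
#' population pyramid, emulating the structure of the claims-, census-
#' and survey-based inputs of a national diabetes projection:
#' \itemize{
#'   \item log-incidence = sex-specific natural-cubic-spline age shape
#'     (rising steeply through midlife to a plateau near age 70) plus a
#'     sex-specific linear calendar trend, flat before the trend
#'     reference year 2015 (no trend information exists before the first
#'     observed year, matching the projection's own pre-2015 rule);
#'   \item mortality = Gompertz `a * exp(b * age)` with a per-year
#'     improvement factor;
#'   \item MRR = piecewise-linear base profile declining from about 3 at
#'     age 30 to about 1.3 at age 90, times `0.98^(year - 2010)`,
#'     floored at 1 (constant before 2010);
#'   \item population = anchored age pyramid with configurable aging
#'     drift and growth, split by sex with a female surplus at old ages.
#' }
#' The incidence age shape is constructed as a linear combination of the
#' same natural-spline basis used by [fit_incidence_trend()] for the
#' standard age groups, so the generating surface lies exactly in the
#' trend model's span and noise-free fits recover it.
#'
#' Given the same `(params, seed)` the returned laws are identical;
#' different seeds jitter the anchor rates, trends, mortality level and
#' MRR multiplicatively to produce distinct admissible truths.
#'
#' @param params Named list overriding entries of the documented default
#'   parameter set (see the vignette).
#' @param seed Integer seed for the jitter draws, or `NULL` for no jitter.
#' @return An object of class `ground_truth`: list of vectorized laws
#'   `incidence(age, year, sex)`, `mortality(age, year, sex)`,
#'   `mrr(age, year, sex)`, `population(age, year, sex)`, plus `p18`,
#'   `spec` (the [spline_spec()] used), and the resolved parameters.
#' @export
generate_ground_truth <- function(params = list(), seed = 1) {
  p <- utils::modifyList(default_truth_params(), params)
  check_truth_params(p)
  jit <- with_seed(seed, list(
    anchors = list(male = stats::rnorm(length(p$anchor_ages), 0, p$anchor_jitter_sd),
                   female = stats::rnorm(length(p$anchor_ages), 0, p$anchor_jitter_sd)),
    gamma = list(male = stats::rnorm(1, 0, p$gamma_jitter_sd),
                 female = stats::rnorm(1, 0, p$gamma_jitter_sd)),
    mort = list(male = stats::rnorm(1, 0, p$mortality_jitter_sd),
                female = stats::rnorm(1, 0, p$mortality_jitter_sd)),
    mrr = stats::rnorm(length(p$mrr_values), 0, p$mrr_jitter_sd)
  ))
  if (is.null(seed)) {
    zeros <- function(n) rep(0, n)
    jit <- list(anchors = list(male = zeros(length(p$anchor_ages)),
                               female = zeros(length(p$anchor_ages))),
                gamma = list(male = 0, female = 0),
                mort = list(male = 0, female = 0),
                mrr = zeros(length(p$mrr_values)))
  }
  spec <- default_spline_spec(p$anchor_ages,
                              p$trend_ref_year:(p$trend_ref_year + 6))
  # age-shape coefficients: least-squares projection of the (jittered)
  # log anchor rates onto the natural-spline age basis
  Xa <- cbind(1, splines::ns(p$anchor_ages, knots = spec$age_knots,
                             Boundary.knots = spec$age_boundary))
  beta <- lapply(stats::setNames(c("male", "female"), c("male", "female")),
                 function(s) {
                   qr.coef(qr(Xa), log(p$anchor_rates[[s]]) + jit$anchors[[s]])
                 })
  gamma <- list(male = p$gamma$male * exp(jit$gamma$male),
                female = p$gamma$female * exp(jit$gamma$female))
  mort_a <- list(male = p$gompertz_a$male * exp(jit$mort$male),
                 female = p$gompertz_a$female * exp(jit$mort$female))
  mrr_base <- 1 + (p$mrr_values - 1) * exp(jit$mrr)
  ref <- p$trend_ref_year

  incidence <- function(age, year, sex) {
    sex <- match.arg(sex, c("male", "female"))
    n <- max(length(age), length(year))
    age <- rep_len(as.numeric(age), n)
    year <- rep_len(as.numeric(year), n)
    B <- cbind(1, splines::ns(age, knots = spec$age_knots,
                              Boundary.knots = spec$age_boundary))
    exp(drop(B %*% beta[[sex]]) + gamma[[sex]] * (pmax(year, ref) - ref))
  }
  mortality <- function(age, year, sex) {
    sex <- match.arg(sex, c("male", "female"))
    n <- max(length(age), length(year))
    age <- rep_len(as.numeric(age), n)
    year <- rep_len(as.numeric(year), n)
    mort_a[[sex]] * exp(p$gompertz_b * age) *
      p$mortality_improvement^(year - p$base_year)
  }
  mrr <- function(age, year, sex) {
    n <- max(length(age), length(year))
    age <- rep_len(as.numeric(age), n)
    year <- rep_len(as.numeric(year), n)
    base <- stats::approx(p$mrr_ages, mrr_base, xout = age, rule = 2)$y
    pmax(1, base * p$mrr_annual_factor^(pmax(year - p$base_year, 0)))
  }
  population <- function(age, year, sex) {
    sex <- match.arg(sex, c("male", "female"))
    n <- max(length(age), length(year))
    age <- rep_len(as.numeric(age), n)
    year <- rep_len(as.numeric(year), n)
    shifted <- pmax(age - p$pop_aging_drift * (year - p$base_year),
                    p$pop_anchor_ages[1L])
    base <- stats::approx(p$pop_anchor_ages, p$pop_anchor_counts,
                          xout = pmin(shifted, max(p$pop_anchor_ages)),
                          rule = 2)$y
    male_share <- pmax(0.40, 0.495 - 0.0027 * pmax(age - 60, 0))
    share <- if (sex == "male") male_share else 1 - male_share
    base * p$pop_growth^(year - p$base_year) * share
  }

  structure(list(incidence = incidence, mortality = mortality, mrr = mrr,
                 population = population, p18 = p$p18, spec = spec,
                 beta = beta, gamma = gamma, params = p),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<synthetic ground truth>\n")
  cat(sprintf("  log-incidence trend per year: male %+.4f, female %+.4f\n",
              x$gamma$male, x$gamma$female))
  cat(sprintf("  incidence at (age 57, 2015): male %.4f, female %.4f\n",
              x$incidence(57, 2015, "male"), x$incidence(57, 2015, "female")))
  invisible(x)
}

#' Extract one sex's rate laws from a ground truth
#'
#' Returns the three rate laws of one sex as plain functions of
#' `(age, year)`, the form consumed by [cohort_microsimulation()].
#'
#' @param truth A [generate_ground_truth()] result.
#' @param sex `"male"` or `"female"`.
#' @return List of functions `incidence`, `mortality`, `mrr`.
#' @export
truth_laws <- function(truth, sex) {
  force(sex)
  list(incidence = function(age, year) truth$incidence(age, year, sex),
       mortality = function(age, year) truth$mortality(age, year, sex),
       mrr = function(age, year) truth$mrr(age, year, sex))
}

group_age_range <- function(age_group, max_age = 100) {
  if (grepl("^[0-9]+-[0-9]+$", age_group)) {
    lo <- as.numeric(sub("-.*$", "", age_group))
    hi <- as.numeric(sub("^.*-", "", age_group))
  } else if (grepl("^[0-9]+\\+$", age_group)) {
    lo <- as.numeric(sub("\\+$", "", age_group))
    hi <- max_age
  } else {
    stop("unparseable age group label: ", age_group, call. = FALSE)
  }
  lo:hi
}

#' Sample grouped incidence estimates from a ground truth
#'
#' Emulates published claims-based estimates: sex-specific rates for the
#' adult age groups for each year separately.  In the default
#' `group_rate = "weighted"` mode the group rate is the person-time
#' weighted mean of the true rate over the group's single ages, using the
#' synthetic population as weights; `"midpoint"` evaluates the true rate
#' at the group's representative age instead (exact for midpoint-based
#' fitting, used by the noise-free recovery checks).  Multiplicative
#' log-normal noise is applied on top.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param age_groups Group tokens (default [standard_age_groups()]).
#' @param years Estimate years (default 2015:2021).
#' @param noise_sd Log-scale standard deviation of the estimate noise
#'   (>= 0; default 0.05).
#' @param seed Seed for the noise draws (`NULL` = use the current RNG
#'   stream).
#' @param group_rate `"weighted"` or `"midpoint"` (see above).
#' @param pandemic_dip Optional factor < 1 applied to all year-2020 rates
#'   to emulate the under-ascertainment dip of the pandemic year
#'   (default `NULL` = off).
#' @param open_age Representative age of the open-ended group in
#'   `"midpoint"` mode.
#' @return Data frame with columns `sex`, `age_group`, `year`, `rate`
#'   (per person-year); 2 sexes x 5 groups x 7 years = 70 rows by default.
#' @export
sample_incidence_estimates <- function(truth, age_groups = standard_age_groups(),
                                       years = 2015:2021, noise_sd = 0.05,
                                       seed = NULL,
                                       group_rate = c("weighted", "midpoint"),
                                       pandemic_dip = NULL, open_age = 85) {
  group_rate <- match.arg(group_rate)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  grid <- expand.grid(sex = c("male", "female"), age_group = age_groups,
                      year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rate <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    s <- grid$sex[k]; g <- grid$age_group[k]; y <- grid$year[k]
    if (group_rate == "midpoint") {
      rate[k] <- truth$incidence(midpoint_of(g, open_age), y, s)
    } else {
      ages <- group_age_range(g)
      w <- truth$population(ages, y, s)
      rate[k] <- sum(w * truth$incidence(ages, y, s)) / sum(w)
    }
  }
  if (!is.null(pandemic_dip)) {
    rate[grid$year == 2020] <- rate[grid$year == 2020] * pandemic_dip
  }
  noise <- with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  data.frame(sex = grid$sex, age_group = grid$age_group, year = grid$year,
             rate = rate * exp(noise), stringsAsFactors = FALSE)
}

#' Discrete-time cohort microsimulation (numerical oracle)
#'
#' Independent check of the characteristic integrator: an explicit Euler
#' forward recursion on the state occupancies of the illness-death model
#' rather than on prevalence.  At each step the unknown mortality of the
#' unaffected is recovered from the substitution identity
#' `m0 = m / (p (MRR - 1) + 1)` and `m1 = MRR * m0`; then
#' `H <- H (1 - (i + m0) dt)` and `I <- I (1 - m1 dt) + H_old i dt`,
#' with prevalence `p = I / (H + I)`.
#'
#' @param incidence,mortality,mrr Rate inputs for one sex: vectorized
#'   functions of `(age, year)`, [rate_surface()] / [mrr_schedule()]
#'   objects, or scalar constants.
#' @param p0 Starting prevalence in \[0, 1\].
#' @param start_age,start_year,end_year Cohort path; age and calendar
#'   time advance together.
#' @param dt Time step in years (default 0.001).  An error is raised if
#'   any occupancy would turn negative at this step.
#' @return A data frame of class `cohort_trajectory` with columns `time`,
#'   `age`, `year`, `prevalence`.
#' @export
cohort_microsimulation <- function(incidence, mortality, mrr, p0,
                                   start_age, start_year, end_year,
                                   dt = 0.001) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (end_year < start_year) {
    stop("`end_year` must not precede `start_year`", call. = FALSE)
  }
  check_epi_inputs(p = p0, m = 0, mrr = 1)
  fi <- as_rate_function(incidence)
  fm <- as_rate_function(mortality)
  fr <- as_rate_function(mrr)
  delta <- end_year - start_year
  if (delta == 0) {
    return(structure(data.frame(time = 0, age = start_age, year = start_year,
                                prevalence = p0),
                     class = c("cohort_trajectory", "data.frame")))
  }
  n <- ceiling(delta / dt - 1e-9)
  h <- delta / n
  s <- (0:(n - 1L)) * h
  iv <- fi(start_age + s, start_year + s)
  mv <- fm(start_age + s, start_year + s)
  rv <- fr(start_age + s, start_year + s)
  if (any(!is.finite(iv)) || any(iv < 0) || any(!is.finite(mv)) ||
      any(mv < 0) || any(!is.finite(rv)) || any(rv < 1)) {
    stop("rate laws must yield finite i >= 0, m >= 0, MRR >= 1 along the path",
         call. = FALSE)
  }
  H <- 1 - p0
  I <- p0
  p <- numeric(n + 1L)
  p[1L] <- p0
  for (j in seq_len(n)) {
    ptot <- H + I
    pj <- if (ptot > 0) I / ptot else 0
    m0 <- mv[j] / (pj * (rv[j] - 1) + 1)
    m1 <- rv[j] * m0
    if ((iv[j] + m0) * h > 1 || m1 * h > 1) {
      stop(sprintf(paste0("dt = %g too large: occupancies would become ",
                          "negative at age %.2f, year %.2f"),
                   h, start_age + s[j], start_year + s[j]), call. = FALSE)
    }
    Hold <- H
    H <- H * (1 - (iv[j] + m0) * h)
    I <- I * (1 - m1 * h) + Hold * iv[j] * h
    p[j + 1L] <- I / (H + I)
  }
  sout <- (0:n) * h
  structure(data.frame(time = sout, age = start_age + sout,
                       year = start_year + sout, prevalence = p),
            class = c("cohort_trajectory", "data.frame"),
            occupancies = c(H = H, I = I))
}

#' Oracle-built prevalence profile for one calendar year
#'
#' Runs the cohort microsimulation from the entry age (prevalence
#' `truth$p18`) up every attained age of the requested year, giving the
#' ground-truth age-specific prevalence implied by the generating laws.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param year Calendar year of the profile.
#' @param ages Ages of the profile (default 18:100).
#' @param sexes Sexes to include.
#' @param dt Euler step in years.  The default 0.0025 keeps the absolute
#'   discretization error a couple of orders of magnitude below the 1e-2
#'   relative scale at which profiles are compared; the oracle itself
#'   defaults to 0.001 for single-cohort checks.
#' @param incidence Optional override of the incidence law
#'   (`function(age, year, sex)`), e.g. a scenario-modified law.
#' @return Data frame with columns `sex`, `age`, `year`, `prevalence`.
#' @export
oracle_prevalence_profile <- function(truth, year, ages = 18:100,
                                      sexes = c("male", "female"),
                                      dt = 0.0025, incidence = NULL) {
  entry_age <- min(ages)
  rows <- list()
  for (s in sexes) {
    laws <- truth_laws(truth, s)
    if (!is.null(incidence)) {
      fi <- incidence
      laws$incidence <- function(age, yr) fi(age, yr, s)
    }
    prof <- numeric(length(ages))
    for (k in seq_along(ages)) {
      a <- ages[k]
      if (a == entry_age) {
        prof[k] <- truth$p18
      } else {
        traj <- cohort_microsimulation(laws$incidence, laws$mortality,
                                       laws$mrr, truth$p18,
                                       start_age = entry_age,
                                       start_year = year - (a - entry_age),
                                       end_year = year, dt = dt)
        prof[k] <- traj$prevalence[nrow(traj)]
      }
    }
    rows[[s]] <- data.frame(sex = s, age = ages, year = year,
                            prevalence = prof, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the five synthetic input tables (plus a run configuration)
#'
#' Materializes a full synthetic study input set in `dir`:
#' `incidence_estimates.csv` (per-1000 person-years, as claims-based
#' estimates are typically published), `prevalence.csv` (baseline
#' prevalence in the base year, from the cohort oracle),
#' `mortality.csv`, `mrr.csv` (baseline MRR profile) and
#' `population.csv`, together with `config.yaml` recording grids, units,
#' seeds and scenario names so the command-line pipeline can run
#' end-to-end without further arguments.
#'
#' @param dir Output directory (created if needed).
#' @param params,seed Passed to [generate_ground_truth()].
#' @param noise_sd,group_rate,pandemic_dip Passed to
#'   [sample_incidence_estimates()] (estimate noise uses `seed + 1`).
#' @param ages,years Grids for the gridded tables.
#' @param profile_dt Euler step for the baseline-prevalence oracle run.
#' @return Invisibly, a list with the file paths and the `truth` object.
#' @export
write_synthetic_inputs <- function(dir, params = list(), seed = 1,
                                   noise_sd = 0.05,
                                   group_rate = "weighted",
                                   pandemic_dip = NULL,
                                   ages = 18:100, years = 2010:2040,
                                   profile_dt = 0.0025) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_ground_truth(params, seed)
  base_year <- truth$params$base_year

  est <- sample_incidence_estimates(truth, noise_sd = noise_sd,
                                    seed = seed + 1L,
                                    group_rate = group_rate,
                                    pandemic_dip = pandemic_dip)
  est$rate <- est$rate * 1000
  paths <- list(incidence_estimates = file.path(dir, "incidence_estimates.csv"))
  write_rate_table(est, paths$incidence_estimates)

  baseline <- oracle_prevalence_profile(truth, base_year, ages = ages,
                                        dt = profile_dt)
  paths$prevalence <- file.path(dir, "prevalence.csv")
  write_rate_table(baseline, paths$prevalence)

  grid <- expand.grid(sex = c("male", "female"), age = ages, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mort <- grid
  mort$rate <- NA_real_
  for (s in c("male", "female")) {
    k <- mort$sex == s
    mort$rate[k] <- truth$mortality(mort$age[k], mort$year[k], s)
  }
  paths$mortality <- file.path(dir, "mortality.csv")
  write_rate_table(mort[c("sex", "age", "year", "rate")], paths$mortality)

  mrrdf <- expand.grid(sex = c("male", "female"), age = ages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mrrdf$mrr <- truth$mrr(mrrdf$age, base_year, "male")  # base profile is sex-shared
  paths$mrr <- file.path(dir, "mrr.csv")
  write_rate_table(mrrdf[c("sex", "age", "mrr")], paths$mrr)

  pop <- grid
  pop$count <- NA_real_
  for (s in c("male", "female")) {
    k <- pop$sex == s
    pop$count[k] <- truth$population(pop$age[k], pop$year[k], s)
  }
  paths$population <- file.path(dir, "population.csv")
  write_rate_table(pop[c("sex", "age", "year", "count")], paths$population)

  config <- list(
    base_year = base_year,
    report_start = truth$params$trend_ref_year,
    horizon = max(years),
    observed_end = 2021,
    min_age = min(ages), max_age = max(ages),
    step = 0.1,
    open_age = 85,
    mrr_annual_factor = truth$params$mrr_annual_factor,
    rate_units = list(incidence_estimates = "per1000", mortality = "per1"),
    scenarios = scenario_names(),
    seed = seed, noise_sd = noise_sd, group_rate = group_rate
  )
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, paths$config)
  invisible(c(paths, list(truth = truth)))
}
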