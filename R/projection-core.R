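#' Excess mortality term of the illness-death model
#'
#' In the illness-death model the prevalence dynamics involve the
#' mortality difference `p * (m1 - m0)` between people with and without
#' the condition.  Because `m0` (mortality of the unaffected) is usually
#' unknown, this difference is replaced by the mathematically equivalent
#' expression
#' \deqn{\frac{p\,(MRR - 1)\,m}{p\,(MRR - 1) + 1},}
#' which only requires the general-population mortality `m` and the
#' mortality rate ratio `MRR = m1 / m0`.
#'
#' @param p Prevalence proportion(s) in \[0, 1\].
#' @param m General-population mortality rate(s), per person-year, >= 0.
#' @param mrr Mortality rate ratio(s), >= 1.
#' @return Non-negative rate per person-year; strictly less than `m`
#'   whenever `p < 1`.
#' @export
excess_mortality_term <- function(p, m, mrr) {
  check_epi_inputs(p = p, m = m, mrr = mrr)
  p * (mrr - 1) * m / (p * (mrr - 1) + 1)
}

#' Right-hand side of the prevalence equation
#'
#' The temporal change of prevalence along the age-time direction is
#' \deqn{\partial p = (1 - p)\,[\,i - p\,(m_1 - m_0)\,],}
#' with `p (m1 - m0)` expressed through [excess_mortality_term()].
#'
#' @inheritParams excess_mortality_term
#' @param i Incidence rate(s) per person-year, >= 0.
#' @return Rate of change of prevalence per year.
#' @export
prevalence_rhs <- function(p, i, m, mrr) {
  check_epi_inputs(p = p, m = m, mrr = mrr, i = i)
  prevalence_rhs_unchecked(p, i, m, mrr)
}

# Unvalidated rhs used inside the integrator, where Runge-Kutta interior
# stages may momentarily leave [0, 1]; prevalence is clamped first.
prevalence_rhs_unchecked <- function(p, i, m, mrr) {
  p <- pmin(pmax(p, 0), 1)
  ex <- p * (mrr - 1) * m / (p * (mrr - 1) + 1)
  (1 - p) * (i - ex)
}

check_epi_inputs <- function(p, m, mrr, i = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("prevalence `p` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("mortality `m` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(mrr)) || any(mrr < 1)) {
    stop("mortality rate ratio `mrr` must be finite and >= 1", call. = FALSE)
  }
  if (!is.null(i) && (any(!is.finite(i)) || any(i < 0))) {
    stop("incidence `i` must be finite and >= 0", call. = FALSE)
  }
  invisible(NULL)
}

# Evaluate the three rate inputs along a characteristic and return the rhs.
# `incidence` and `mortality` are rate surfaces (or anything eval_surface
# accepts through as_rate_function upstream); `mrr` is an mrr_schedule.
char_rhs <- function(p, age, year, incidence, mortality, mrr) {
  i <- eval_surface(incidence, age, year)
  m <- eval_surface(mortality, age, year)
  r <- mrr_at(mrr, age, year)
  bad <- !is.finite(i) | !is.finite(m) | !is.finite(r)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("non-finite rate evaluation at age %.3f, year %.3f",
                 rep_len(age, length(p))[k], rep_len(year, length(p))[k]),
         call. = FALSE)
  }
  prevalence_rhs_unchecked(p, i, m, r)
}

# One classical RK4 update of the prevalence vector `p` for the bundle of
# characteristics currently at ages `age` and years `year`, step `h`.
rk4_step <- function(p, age, year, h, incidence, mortality, mrr) {
  k1 <- char_rhs(p,              age,         year,         incidence, mortality, mrr)
  k2 <- char_rhs(p + h / 2 * k1, age + h / 2, year + h / 2, incidence, mortality, mrr)
  k3 <- char_rhs(p + h / 2 * k2, age + h / 2, year + h / 2, incidence, mortality, mrr)
  k4 <- char_rhs(p + h * k3,     age + h,     year + h,     incidence, mortality, mrr)
  pmin(pmax(p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
}

#' Integrate the prevalence equation along one characteristic
#'
#' Along the characteristic line age = start_age + s, year = start_year + s
#' the prevalence partial differential equation reduces to an ordinary
#' differential equation, which is integrated with the classical
#' fourth-order Runge-Kutta scheme.  Prevalence is clipped to \[0, 1\]
#' after every step to guard against overshoot at coarse steps.
#'
#' @param p_start Initial prevalence proportion at (start_age, start_year).
#' @param start_age,start_year Starting point of the characteristic.
#' @param end_year Calendar year at which integration stops
#'   (>= `start_year`).
#' @param incidence,mortality [rate_surface()] objects (evaluated with
#'   edge clamping outside their hull).
#' @param mrr An [mrr_schedule()].
#' @param step Integration step in years (> 0).  The actual step used is
#'   `(end_year - start_year) / n` with `n = ceiling((end_year - start_year)
#'   / step)`, so the path always ends exactly at `end_year`.
#' @return A data frame of class `characteristic_path` with columns
#'   `age`, `year` and `prevalence` at every integration node.
#' @export
integrate_characteristic <- function(p_start, start_age, start_year, end_year,
                                     incidence, mortality, mrr, step = 0.1) {
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (end_year < start_year) {
    stop("`end_year` must not precede `start_year`", call. = FALSE)
  }
  check_epi_inputs(p = p_start, m = 0, mrr = 1)
  delta <- end_year - start_year
  if (delta == 0) {
    return(new_characteristic_path(start_age, start_year, p_start, step))
  }
  n <- ceiling(delta / step - 1e-9)
  h <- delta / n
  p <- numeric(n + 1L)
  p[1L] <- p_start
  for (j in seq_len(n)) {
    s <- (j - 1L) * h
    p[j + 1L] <- rk4_step(p[j], start_age + s, start_year + s, h,
                          incidence, mortality, mrr)
  }
  s <- (0:n) * h
  new_characteristic_path(start_age + s, start_year + s, p, h)
}

new_characteristic_path <- function(age, year, prevalence, step) {
  structure(data.frame(age = age, year = year, prevalence = prevalence),
            class = c("characteristic_path", "data.frame"),
            step = step)
}

# Integrate a bundle of characteristics year by year and return the
# prevalence at integer-year offsets 0..n_years as a matrix
# [n_characteristics x (n_years + 1)].  All characteristics advance in
# lockstep; `age0`/`year0` are vectors (recycled to a common length).
rk4_yearly_batch <- function(p0, age0, year0, n_years, k_per_year,
                             incidence, mortality, mrr) {
  n <- max(length(p0), length(age0), length(year0))
  p <- rep_len(p0, n)
  age0 <- rep_len(age0, n)
  year0 <- rep_len(year0, n)
  h <- 1 / k_per_year
  out <- matrix(NA_real_, nrow = n, ncol = n_years + 1L)
  out[, 1L] <- p
  for (y in seq_len(n_years)) {
    for (j in seq_len(k_per_year)) {
      s <- (y - 1L) + (j - 1L) * h
      p <- rk4_step(p, age0 + s, year0 + s, h, incidence, mortality, mrr)
    }
    out[, y + 1L] <- p
  }
  out
}

#' Project a prevalence surface from an initial age profile
#'
#' Launches one characteristic from every age node of the first year line
#' and one from the minimum-age node of every subsequent year line
#' (entering cohorts, held at `boundary_prevalence`), integrates the
#' prevalence equation along each with RK4, and assembles the values at
#' the rectangular (age, year) grid nodes.  Because every characteristic
#' starts on a grid node and both grids have unit spacing, each grid node
#' is hit exactly by one characteristic; no resampling error is incurred.
#'
#' @param initial_prevalence Numeric vector of prevalence over `ages` at
#'   the first year (or a function of age).
#' @param boundary_prevalence Prevalence assigned to cohorts entering at
#'   the minimum age in every later year.  Defaults to the initial
#'   profile's value at the minimum age.
#' @param incidence,mortality [rate_surface()] objects for one sex.
#' @param mrr An [mrr_schedule()].
#' @param ages,years Unit-spaced, strictly increasing grids (e.g. `18:100`
#'   and `2010:2040`).
#' @param step Integration step in years; the effective step is
#'   `1 / ceiling(1 / step)` so that integration nodes land exactly on
#'   calendar years.
#' @return A [prevalence_surface()] on the requested grid; its first-year
#'   column equals `initial_prevalence` exactly and its minimum-age row
#'   equals `boundary_prevalence` exactly.
#' @export
project_prevalence_surface <- function(initial_prevalence,
                                       boundary_prevalence = NULL,
                                       incidence, mortality, mrr,
                                       ages = 18:100, years, step = 0.1) {
  if (any(abs(diff(ages) - 1) > 1e-9) || any(abs(diff(years) - 1) > 1e-9)) {
    stop("`ages` and `years` must be unit-spaced grids", call. = FALSE)
  }
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (is.function(initial_prevalence)) {
    initial_prevalence <- initial_prevalence(ages)
  }
  if (length(initial_prevalence) != length(ages)) {
    stop("`initial_prevalence` must cover the age grid", call. = FALSE)
  }
  check_epi_inputs(p = initial_prevalence, m = 0, mrr = 1)
  if (is.null(boundary_prevalence)) {
    boundary_prevalence <- initial_prevalence[1L]
  }
  check_epi_inputs(p = boundary_prevalence, m = 0, mrr = 1)
  na <- length(ages)
  ny <- length(years)
  k <- ceiling(1 / step - 1e-9)
  P <- matrix(NA_real_, nrow = na, ncol = ny)

  # characteristics launched from the first-year line
  base <- rk4_yearly_batch(initial_prevalence, ages, years[1L], ny - 1L, k,
                           incidence, mortality, mrr)
  for (t in 0:(ny - 1L)) {
    i_idx <- seq_len(na)[seq_len(na) - t >= 1L]
    P[i_idx, t + 1L] <- base[i_idx - t, t + 1L]
  }

  # entering cohorts at the minimum age of each later year; cohort m
  # (1-based) starts at year offset m and reaches age ages[i] at year
  # offset m + i - 1, i.e. grid node (row i, column m + i)
  if (ny > 1L) {
    coh <- rk4_yearly_batch(boundary_prevalence, ages[1L], years[-1L],
                            max(ny - 2L, 0L), k, incidence, mortality, mrr)
    for (m in seq_len(ny - 1L)) {
      i_max <- min(na, ny - m)
      idx <- seq_len(i_max)
      P[cbind(idx, m + idx)] <- coh[m, idx]
    }
  }
  if (any(is.na(P))) {
    stop("internal geometry error: grid nodes not covered by characteristics",
         call. = FALSE)
  }
  prevalence_surface(incidence$sex, ages, years, P)
}
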