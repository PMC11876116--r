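#' Mortality rate ratio schedule
#'
#' The mortality rate ratio (MRR) compares mortality among people with
#' the condition to mortality among people without it (m1/m0).  The
#' schedule stores a baseline age profile (piecewise linear in age,
#' constant beyond its end points) together with a multiplicative annual
#' decline factor, reflecting the secular narrowing of the mortality gap:
#' evaluated MRR = max(floor, base_mrr(age) * annual_factor^(year - base_year)).
#'
#' The default decline of 2\% per year (`annual_factor = 0.98`) encodes
#' the assumption of a steadily improving survival of people with the
#' condition over the projection window.  The floor at 1 prevents the
#' decline from turning the condition protective.
#'
#' @param sex `"male"` or `"female"`.
#' @param base_year Calendar year at which `base_mrr` applies (default 2010).
#' @param ages Strictly increasing ages (years) at which `base_mrr` is given.
#' @param base_mrr MRR values at `ages` in the base year; all must be >= 1.
#' @param annual_factor Multiplicative per-year factor in (0, 1]; default 0.98.
#' @param floor Minimum admissible MRR (default 1).
#' @return An object of class `mrr_schedule`.
#' @export
mrr_schedule <- function(sex, base_year = 2010, ages, base_mrr,
                         annual_factor = 0.98, floor = 1) {
  sex <- match.arg(sex, c("male", "female"))
  ages <- as.numeric(ages)
  base_mrr <- as.numeric(base_mrr)
  if (length(ages) != length(base_mrr) || length(ages) < 1L) {
    stop("`ages` and `base_mrr` must have equal positive length", call. = FALSE)
  }
  if (length(ages) > 1L && any(diff(ages) <= 0)) {
    stop("`ages` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(base_mrr)) || any(base_mrr < 1)) {
    stop("`base_mrr` must be finite and >= 1 everywhere", call. = FALSE)
  }
  if (!is.finite(annual_factor) || annual_factor <= 0 || annual_factor > 1) {
    stop("`annual_factor` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(sex = sex, base_year = as.numeric(base_year), ages = ages,
                 base_mrr = base_mrr, annual_factor = annual_factor,
                 floor = floor),
            class = "mrr_schedule")
}

#' Evaluate an MRR schedule
#'
#' Returns `max(floor, base_mrr(age) * annual_factor^(year - base_year))`,
#' with `base_mrr(age)` interpolated piecewise-linearly in age and held
#' constant beyond the profile's end points.
#'
#' @param schedule An [mrr_schedule()].
#' @param age,year Numeric vectors (recycled to a common length).
#' @return Numeric vector of mortality rate ratios (>= `floor`).
#' @export
mrr_at <- function(schedule, age, year) {
  n <- max(length(age), length(year))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  if (any(year < schedule$base_year - 1e-9)) {
    stop(sprintf("MRR schedule for %s is undefined before its base year %g",
                 schedule$sex, schedule$base_year), call. = FALSE)
  }
  base <- if (length(schedule$ages) == 1L) {
    rep_len(schedule$base_mrr, n)
  } else {
    stats::approx(schedule$ages, schedule$base_mrr, xout = age, rule = 2)$y
  }
  pmax(schedule$floor, base * schedule$annual_factor^(year - schedule$base_year))
}

#' @export
print.mrr_schedule <- function(x, ...) {
  cat(sprintf("<MRR schedule: %s, base year %g, annual factor %g, floor %g>\n",
              x$sex, x$base_year, x$annual_factor, x$floor))
  cat(sprintf("  base MRR %g-%g over ages %g-%g\n",
              min(x$base_mrr), max(x$base_mrr), min(x$ages), max(x$ages)))
  invisible(x)
}
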