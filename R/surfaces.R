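#' Rate surface over age and calendar year
#'
#' A `rate_surface` stores a per-sex grid of rates (per person-year) over
#' age and calendar year, with continuous support via bilinear
#' interpolation.  Evaluation outside the grid hull is clamped to the
#' nearest edge, so a surface defined on ages 18--100 can safely be
#' queried along a characteristic that runs beyond age 100.
#'
#' @param sex `"male"` or `"female"`.
#' @param ages Strictly increasing numeric vector of ages in years.
#' @param years Strictly increasing numeric vector of calendar years.
#' @param values Numeric matrix of rates, `length(ages)` rows by
#'   `length(years)` columns; all values must be finite and non-negative.
#' @return An object of class `rate_surface`.
#' @seealso [eval_surface()], [rate_surface_from_function()]
#' @export
rate_surface <- function(sex, ages, years, values) {
  new_surface(sex, ages, years, values,
              class = "rate_surface", lower = 0, upper = Inf)
}

#' Prevalence surface over age and calendar year
#'
#' Like [rate_surface()] but holding prevalence proportions, which must
#' lie in \[0, 1\].
#'
#' @inheritParams rate_surface
#' @param values Numeric matrix of prevalence proportions in \[0, 1\].
#' @return An object of class `prevalence_surface`.
#' @export
prevalence_surface <- function(sex, ages, years, values) {
  new_surface(sex, ages, years, values,
              class = c("prevalence_surface", "rate_surface"),
              lower = 0, upper = 1)
}

new_surface <- function(sex, ages, years, values, class, lower, upper) {
  sex <- match.arg(sex, c("male", "female"))
  ages <- as.numeric(ages)
  years <- as.numeric(years)
  if (length(ages) < 1L || any(diff(ages) <= 0)) {
    stop("`ages` must be a strictly increasing vector", call. = FALSE)
  }
  if (length(years) < 1L || any(diff(years) <= 0)) {
    stop("`years` must be a strictly increasing vector", call. = FALSE)
  }
  values <- matrix(as.numeric(values), nrow = length(ages), ncol = length(years))
  if (any(!is.finite(values))) {
    stop("surface values must all be finite", call. = FALSE)
  }
  if (any(values < lower) || any(values > upper)) {
    stop(sprintf("surface values must lie in [%g, %g]", lower, upper),
         call. = FALSE)
  }
  structure(list(sex = sex, ages = ages, years = years, values = values),
            class = class)
}

#' Build a surface by evaluating a function on a grid
#'
#' @param f A vectorized function `f(age, year)` returning rates (or
#'   prevalences for `prevalence_surface_from_function`).
#' @inheritParams rate_surface
#' @return A [rate_surface()] (resp. [prevalence_surface()]).
#' @export
rate_surface_from_function <- function(f, sex, ages, years) {
  grid <- expand.grid(age = ages, year = years)
  rate_surface(sex, ages, years, f(grid$age, grid$year))
}

#' @rdname rate_surface_from_function
#' @export
prevalence_surface_from_function <- function(f, sex, ages, years) {
  grid <- expand.grid(age = ages, year = years)
  prevalence_surface(sex, ages, years, f(grid$age, grid$year))
}

#' Evaluate a surface at arbitrary (age, year) points
#'
#' Bilinear interpolation between grid nodes; queries outside the grid
#' hull are clamped to the nearest edge.  `age` and `year` are recycled
#' to a common length.
#'
#' @param surface A [rate_surface()] or [prevalence_surface()].
#' @param age,year Numeric vectors of evaluation points.
#' @return Numeric vector of interpolated values.
#' @export
eval_surface <- function(surface, age, year) {
  n <- max(length(age), length(year))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  ax <- surface$ages
  yx <- surface$years
  a <- pmin(pmax(age, ax[1L]), ax[length(ax)])
  y <- pmin(pmax(year, yx[1L]), yx[length(yx)])
  ia <- if (length(ax) == 1L) rep(1L, n) else
    pmin(pmax(findInterval(a, ax), 1L), length(ax) - 1L)
  iy <- if (length(yx) == 1L) rep(1L, n) else
    pmin(pmax(findInterval(y, yx), 1L), length(yx) - 1L)
  wa <- if (length(ax) == 1L) rep(0, n) else
    (a - ax[ia]) / (ax[ia + 1L] - ax[ia])
  wy <- if (length(yx) == 1L) rep(0, n) else
    (y - yx[iy]) / (yx[iy + 1L] - yx[iy])
  v <- surface$values
  na <- nrow(v)
  ia2 <- if (length(ax) == 1L) ia else ia + 1L
  iy2 <- if (length(yx) == 1L) iy else iy + 1L
  # index into the matrix by flat position for speed
  v00 <- v[ia  + (iy  - 1L) * na]
  v10 <- v[ia2 + (iy  - 1L) * na]
  v01 <- v[ia  + (iy2 - 1L) * na]
  v11 <- v[ia2 + (iy2 - 1L) * na]
  (1 - wa) * (1 - wy) * v00 + wa * (1 - wy) * v10 +
    (1 - wa) * wy * v01 + wa * wy * v11
}

#' @export
print.rate_surface <- function(x, ...) {
  kind <- if (inherits(x, "prevalence_surface")) "prevalence" else "rate"
  cat(sprintf("<%s surface: %s, ages %g-%g (%d), years %g-%g (%d)>\n",
              kind, x$sex, min(x$ages), max(x$ages), length(x$ages),
              min(x$years), max(x$years), length(x$years)))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a surface to a long-format table
#'
#' @param surface A [rate_surface()] or [prevalence_surface()].
#' @return A data frame with columns `sex`, `age`, `year` and `rate`
#'   (or `prevalence` for prevalence surfaces).
#' @export
surface_to_table <- function(surface) {
  value_col <- if (inherits(surface, "prevalence_surface")) "prevalence" else "rate"
  out <- expand.grid(age = surface$ages, year = surface$years,
                     KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(sex = surface$sex, age = out$age, year = out$year,
                    value = as.vector(surface$values),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "value"] <- value_col
  out
}

# Coerce a rate description (function, surface, or scalar) into a
# vectorized function of (age, year).  Used so the cohort oracle and the
# characteristic integrator can consume identical inputs.
as_rate_function <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "rate_surface")) {
    force(x)
    return(function(age, year) eval_surface(x, age, year))
  }
  if (inherits(x, "mrr_schedule")) {
    force(x)
    return(function(age, year) mrr_at(x, age, year))
  }
  if (is.numeric(x) && length(x) == 1L) {
    val <- as.numeric(x)
    return(function(age, year) rep_len(val, max(length(age), length(year))))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a rate function", call. = FALSE)
}
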