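#' Representative age of a grouped age interval
#'
#' Grouped incidence estimates are modeled at a single representative age
#' per group: closed intervals (`"18-34"`) map to their arithmetic
#' midpoint and the open-ended top group (`"80+"`) maps to a configurable
#' representative age.
#'
#' @param age_group Character vector of group tokens, `"lo-hi"` or `"lo+"`.
#' @param open_age Representative age for open-ended `"lo+"` groups
#'   (default 85).  Results for the oldest ages are mildly sensitive to
#'   this choice; see the package vignette.
#' @return Numeric vector of representative ages.
#' @export
midpoint_of <- function(age_group, open_age = 85) {
  age_group <- as.character(age_group)
  out <- rep(NA_real_, length(age_group))
  closed <- grepl("^[0-9]+-[0-9]+$", age_group)
  open <- grepl("^[0-9]+\\+$", age_group)
  if (any(closed)) {
    lo <- as.numeric(sub("-.*$", "", age_group[closed]))
    hi <- as.numeric(sub("^.*-", "", age_group[closed]))
    out[closed] <- (lo + hi) / 2
  }
  out[open] <- open_age
  if (any(is.na(out))) {
    stop("unparseable age group label(s): ",
         paste(unique(age_group[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Natural cubic spline specification for the incidence trend model
#'
#' The trend model uses a natural (linear-beyond-boundary) cubic spline
#' basis for age with four knots (two boundary, two interior) and for
#' calendar year with one interior knot, crossed with sex up to the
#' three-way interaction.
#'
#' @param age_knots Interior knots for age.
#' @param age_boundary Length-2 boundary knots for age.
#' @param year_knots Interior knot(s) for calendar year.
#' @param year_boundary Length-2 boundary knots for year.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(age_knots, age_boundary, year_knots, year_boundary) {
  age_knots <- as.numeric(age_knots)
  year_knots <- as.numeric(year_knots)
  age_boundary <- as.numeric(age_boundary)
  year_boundary <- as.numeric(year_boundary)
  if (length(age_boundary) != 2L || length(year_boundary) != 2L) {
    stop("boundary knots must have length 2", call. = FALSE)
  }
  if (any(age_knots <= age_boundary[1L]) || any(age_knots >= age_boundary[2L])) {
    stop("age interior knots must lie strictly inside the boundary", call. = FALSE)
  }
  if (any(year_knots <= year_boundary[1L]) || any(year_knots >= year_boundary[2L])) {
    stop("year interior knots must lie strictly inside the boundary", call. = FALSE)
  }
  structure(list(age_knots = age_knots, age_boundary = age_boundary,
                 year_knots = year_knots, year_boundary = year_boundary),
            class = "spline_spec")
}

#' Default spline specification derived from the data
#'
#' Interior age knots at the terciles of the observed representative
#' ages, boundary knots at their range; one interior year knot at the
#' median observed year, boundary knots at the year range.
#'
#' @param midpoints Representative ages present in the data.
#' @param years Calendar years present in the data.
#' @return A [spline_spec()].
#' @export
default_spline_spec <- function(midpoints, years) {
  m <- sort(unique(as.numeric(midpoints)))
  y <- sort(unique(as.numeric(years)))
  spline_spec(age_knots = unname(stats::quantile(m, c(1 / 3, 2 / 3))),
              age_boundary = range(m),
              year_knots = stats::median(y),
              year_boundary = range(y))
}

# Full tensor design matrix: (1, age basis) x (1, year basis) x (1, sex)
# with natural cubic spline bases.  Used by both fitting and prediction
# (and by the synthetic-data generator to construct in-span truths).
trend_design <- function(age, year, sex, spec) {
  n <- max(length(age), length(year), length(sex))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  A <- splines::ns(age, knots = spec$age_knots,
                   Boundary.knots = spec$age_boundary)
  Y <- splines::ns(year, knots = spec$year_knots,
                   Boundary.knots = spec$year_boundary)
  ablock <- cbind(1, A)
  yblock <- cbind(1, Y)
  sblock <- cbind(1, as.numeric(sex == "male"))
  anames <- c("", paste0("age", seq_len(ncol(A))))
  ynames <- c("", paste0("year", seq_len(ncol(Y))))
  snames <- c("", "sexmale")
  cols <- list()
  nms <- character(0)
  for (ks in seq_len(2L)) {
    for (ky in seq_len(ncol(yblock))) {
      for (ka in seq_len(ncol(ablock))) {
        cols[[length(cols) + 1L]] <- ablock[, ka] * yblock[, ky] * sblock[, ks]
        nm <- paste(c(anames[ka], ynames[ky], snames[ks])[
          c(anames[ka], ynames[ky], snames[ks]) != ""], collapse = ":")
        nms <- c(nms, if (nm == "") "(Intercept)" else nm)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nms
  X
}

#' Fit the log-linear spline trend model to grouped incidence estimates
#'
#' Ordinary least squares on the natural logarithm of the incidence rate
#' with a design crossing a natural cubic spline in age (four knots),
#' a natural cubic spline in calendar year (one interior knot) and sex,
#' including all interactions up to the three-way product.
#'
#' @param estimates Data frame with columns `sex` (`"male"`/`"female"`),
#'   `age_group` (`"lo-hi"` or `"lo+"` tokens), `year` and `rate`
#'   (incidence per person-year, > 0).  Groups entirely below age 18 are
#'   dropped (adult-only model).
#' @param spec A [spline_spec()]; by default derived from the data via
#'   [default_spline_spec()].
#' @param open_age Representative age for the open-ended top group.
#' @return An object of class `incidence_trend_model` with elements
#'   `spec`, `coefficients`, `open_age` and `diagnostics` (residual
#'   summary).
#' @export
fit_incidence_trend <- function(estimates, spec = NULL, open_age = 85) {
  required <- c("sex", "age_group", "year", "rate")
  missing_cols <- setdiff(required, names(estimates))
  if (length(missing_cols) > 0L) {
    stop("`estimates` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  est <- estimates[!grepl("^<", as.character(estimates$age_group)), , drop = FALSE]
  est$midpoint <- midpoint_of(est$age_group, open_age = open_age)
  est <- est[est$midpoint >= 18, , drop = FALSE]
  if (any(!is.finite(est$rate) | est$rate <= 0)) {
    stop("all incidence rates must be finite and > 0 (log transform)",
         call. = FALSE)
  }
  if (length(unique(est$year)) < 2L) {
    stop("need >= 2 distinct years to identify the year spline", call. = FALSE)
  }
  if (length(unique(est$midpoint)) < 4L) {
    stop("need >= 4 distinct age midpoints to identify the age spline",
         call. = FALSE)
  }
  if (!all(c("male", "female") %in% est$sex)) {
    stop("both sexes must be present in the estimates", call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- default_spline_spec(est$midpoint, est$year)
  }
  X <- trend_design(est$midpoint, est$year, est$sex, spec)
  if (nrow(X) < ncol(X)) {
    stop(sprintf("fewer observations (%d) than parameters (%d)",
                 nrow(X), ncol(X)), call. = FALSE)
  }
  y <- log(est$rate)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop(sprintf("rank-deficient design (rank %d < %d columns)",
                 qrx$rank, ncol(X)), call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  df_res <- nrow(X) - ncol(X)
  diagnostics <- list(
    n = nrow(X),
    df_residual = df_res,
    sigma = if (df_res > 0) sqrt(sum(resid^2) / df_res) else NA_real_,
    max_abs_residual = max(abs(resid)),
    r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2)
  )
  structure(list(spec = spec, coefficients = coef, open_age = open_age,
                 diagnostics = diagnostics),
            class = "incidence_trend_model")
}

#' Predict incidence from a fitted trend model
#'
#' Evaluates `exp(linear predictor)`; the natural spline bases extend
#' linearly beyond their boundary knots, so extrapolation in calendar
#' year (the trend scenarios) continues the log-linear trend.
#'
#' @param model An [fit_incidence_trend()] result.
#' @param sex,age,year Vectors (recycled to a common length).
#' @return Strictly positive incidence rates per person-year.
#' @export
predict_incidence <- function(model, sex, age, year) {
  if (!inherits(model, "incidence_trend_model")) {
    stop("`model` must be a fitted incidence_trend_model", call. = FALSE)
  }
  X <- trend_design(age, year, sex, model$spec)
  exp(drop(X %*% model$coefficients))
}

#' @export
print.incidence_trend_model <- function(x, ...) {
  cat("<incidence trend model: log-rate ~ ns(age) * ns(year) * sex>\n")
  cat(sprintf("  age knots: %s (boundary %s)\n",
              paste(x$spec$age_knots, collapse = ", "),
              paste(x$spec$age_boundary, collapse = "-")))
  cat(sprintf("  year knots: %s (boundary %s)\n",
              paste(x$spec$year_knots, collapse = ", "),
              paste(x$spec$year_boundary, collapse = "-")))
  cat(sprintf("  %d coefficients; n = %d; residual sd = %.4g\n",
              length(x$coefficients), x$diagnostics$n, x$diagnostics$sigma))
  invisible(x)
}

#' Export / import a fitted trend model as a plain-text document
#'
#' The model is stored as a YAML key-value document holding the spline
#' specification, the representative age of the open-ended group and the
#' named coefficient vector, so fits are reproducible across sessions
#' without serialized binary objects.
#'
#' @param model An `incidence_trend_model`.
#' @param path File path to write to / read from.
#' @return `read_trend_model` returns an `incidence_trend_model`;
#'   `write_trend_model` returns `path` invisibly.
#' @export
write_trend_model <- function(model, path) {
  doc <- list(
    type = "incidence_trend_model",
    spec = list(age_knots = model$spec$age_knots,
                age_boundary = model$spec$age_boundary,
                year_knots = model$spec$year_knots,
                year_boundary = model$spec$year_boundary),
    open_age = model$open_age,
    coefficients = as.list(model$coefficients),
    diagnostics = model$diagnostics
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_trend_model
#' @export
read_trend_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (!identical(doc$type, "incidence_trend_model")) {
    stop("`", path, "` is not an incidence trend model document", call. = FALSE)
  }
  spec <- spline_spec(doc$spec$age_knots, doc$spec$age_boundary,
                      doc$spec$year_knots, doc$spec$year_boundary)
  coef <- unlist(doc$coefficients)
  structure(list(spec = spec, coefficients = coef, open_age = doc$open_age,
                 diagnostics = doc$diagnostics),
            class = "incidence_trend_model")
}
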