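test_that("excess mortality term matches the substitution expression and its limits", {
  # MRR = 1: no differential mortality
  expect_equal(excess_mortality_term(0.10, 0.02, 1), 0)
  # no prevalent cases: no excess term
  expect_equal(excess_mortality_term(0, 0.02, 3), 0)
  # hand evaluation of the rational expression
  expect_equal(excess_mortality_term(0.20, 0.01, 2),
               0.2 * 1 * 0.01 / (0.2 * 1 + 1), tolerance = 1e-15)
  expect_equal(excess_mortality_term(0.20, 0.01, 2), 1 / 600,
               tolerance = 1e-12)
  # bounded by m whenever p < 1
  p <- seq(0, 0.99, by = 0.11)
  expect_true(all(excess_mortality_term(p, 0.03, 2.5) < 0.03))
  expect_true(all(excess_mortality_term(p, 0.03, 2.5) >= 0))
  # domain errors
  expect_error(excess_mortality_term(-0.1, 0.02, 2), "\\[0, 1\\]")
  expect_error(excess_mortality_term(1.1, 0.02, 2), "\\[0, 1\\]")
  expect_error(excess_mortality_term(0.2, -0.01, 2), "mortality")
  expect_error(excess_mortality_term(0.2, 0.01, 0.9), "ratio")
})

test_that("prevalence rhs composes (1 - p) * (i - excess term)", {
  expect_equal(prevalence_rhs(1, 0.05, 0.02, 2), 0)     # (1 - p) vanishes
  expect_equal(prevalence_rhs(0, 0.005, 0.01, 2), 0.005)
  expect_equal(prevalence_rhs(0.2, 0.01, 0.01, 2),
               0.8 * (0.01 - 0.2 * 0.01 / 1.2), tolerance = 1e-15)
  expect_equal(prevalence_rhs(0.2, 0.01, 0.01, 2), 0.0066666667,
               tolerance = 1e-8)
  expect_error(prevalence_rhs(0.2, -0.01, 0.01, 2), "incidence")
})

test_that("characteristics are flat when incidence is zero and MRR is one", {
  inc <- const_surface(0)
  mort <- const_surface(0.02)
  sch <- const_mrr(1)
  path <- integrate_characteristic(0.37, 40, 2010, 2035, inc, mort, sch)
  expect_equal(path$prevalence, rep(0.37, nrow(path)))
  expect_equal(path$age - 40, path$year - 2010)  # lockstep advance
  expect_equal(path$year[nrow(path)], 2035)
  expect_equal(path$age[nrow(path)], 65)
})

test_that("RK4 matches the closed-form constant-incidence solution to 1e-8", {
  inc <- const_surface(0.02)
  mort <- const_surface(0.01)
  sch <- const_mrr(1)
  for (p0 in c(0, 0.1, 0.5)) {
    path <- integrate_characteristic(p0, 30, 2010, 2040, inc, mort, sch,
                                     step = 0.1)
    closed <- 1 - (1 - p0) * exp(-0.02 * (path$year - 2010))
    expect_lt(max(abs(path$prevalence - closed)), 1e-8)
  }
})

test_that("halving the step shrinks the error about 2^4 (RK4 order)", {
  # incidence linear in calendar year (bilinear rep is exact), MRR = 1:
  # dp/ds = (1 - p) (a + b s) has the closed form below
  a <- 0.05; b <- 0.02
  inc <- rate_surface_from_function(function(ag, y) a + b * (y - 2010),
                                    "male", c(0, 120), 2010:2040)
  mort <- const_surface(0.01)
  sch <- const_mrr(1)
  closed <- function(s) 1 - exp(-(a * s + b * s^2 / 2))
  err <- vapply(c(1, 0.5, 0.25), function(h) {
    path <- integrate_characteristic(0, 40, 2010, 2030, inc, mort, sch,
                                     step = h)
    abs(path$prevalence[nrow(path)] - closed(20))
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 10 & ratios < 24))
})

test_that("projected prevalence stays in [0, 1] for random admissible inputs", {
  set.seed(11)
  for (rep in 1:8) {
    ages <- c(0, 60, 120)
    years <- c(2000, 2020, 2040)
    inc <- rate_surface("male", ages, years,
                        matrix(runif(9, 0, 0.3), 3, 3))
    mort <- rate_surface("male", ages, years,
                         matrix(runif(9, 0, 0.3), 3, 3))
    sch <- mrr_schedule("male", 2000, c(0, 120), 1 + runif(2, 0, 3))
    p0 <- runif(1)
    path <- integrate_characteristic(p0, 30, 2000, 2040, inc, mort, sch,
                                     step = 0.25)
    expect_true(all(path$prevalence >= 0 & path$prevalence <= 1))
  }
})

test_that("larger MRR never increases, larger incidence never decreases prevalence", {
  set.seed(13)
  inc <- rate_surface("male", c(18, 100), c(2010, 2040),
                      matrix(runif(4, 0.005, 0.03), 2, 2))
  mort <- rate_surface("male", c(18, 100), c(2010, 2040),
                       matrix(runif(4, 0.01, 0.1), 2, 2))
  low <- const_mrr(1.3, base_year = 2010)
  high <- const_mrr(2.8, base_year = 2010)
  p_low <- integrate_characteristic(0.1, 40, 2010, 2040, inc, mort, low)
  p_high <- integrate_characteristic(0.1, 40, 2010, 2040, inc, mort, high)
  expect_true(all(p_high$prevalence <= p_low$prevalence + 1e-12))

  inc2 <- rate_surface("male", c(18, 100), c(2010, 2040), 1.4 * inc$values)
  p1 <- integrate_characteristic(0.1, 40, 2010, 2040, inc, mort, low)
  p2 <- integrate_characteristic(0.1, 40, 2010, 2040, inc2, mort, low)
  expect_true(all(p2$prevalence >= p1$prevalence - 1e-12))
})

test_that("surface projection honors the initial profile and boundary exactly", {
  ages <- 18:40
  years <- 2010:2025
  init <- seq(0.004, 0.12, length.out = length(ages))
  inc <- const_surface(0.01)
  mort <- const_surface(0.02)
  sch <- const_mrr(1.5, base_year = 2000)

  # zero-length projection returns the initial profile
  s0 <- project_prevalence_surface(init, incidence = inc, mortality = mort,
                                   mrr = sch, ages = ages, years = 2010)
  expect_equal(as.vector(s0$values), init)

  surf <- project_prevalence_surface(init, incidence = inc, mortality = mort,
                                     mrr = sch, ages = ages, years = years)
  expect_s3_class(surf, "prevalence_surface")
  expect_equal(surf$values[, 1], init)                       # base-year line
  expect_equal(surf$values[1, ], rep(init[1], length(years))) # entry-age line
  expect_true(all(surf$values >= 0 & surf$values <= 1))
})

test_that("with zero incidence and MRR = 1 the surface is constant along diagonals", {
  ages <- 18:30
  years <- 2010:2020
  init <- seq(0.05, 0.4, length.out = length(ages))
  surf <- project_prevalence_surface(init, boundary_prevalence = init[1],
                                     incidence = const_surface(0),
                                     mortality = const_surface(0.05),
                                     mrr = const_mrr(1),
                                     ages = ages, years = years)
  for (j in seq_along(years)) {
    t <- j - 1L
    # cohorts present since the base year keep their initial value
    idx <- which(seq_along(ages) - t >= 1L)
    expect_equal(surf$values[idx, j], init[idx - t])
    # entered cohorts carry the boundary value
    if (t >= 1L) {
      ent <- which(seq_along(ages) - t < 1L & seq_along(ages) <= t)
      if (length(ent) > 0) expect_equal(surf$values[ent, j],
                                        rep(init[1], length(ent)))
    }
  }
})
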