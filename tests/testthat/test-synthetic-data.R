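test_that("ground truths are deterministic in (params, seed) and admissible", {
  t1 <- generate_ground_truth(seed = 4)
  t2 <- generate_ground_truth(seed = 4)
  grid <- expand.grid(age = c(20, 45, 70, 95), year = c(2010, 2025, 2040))
  for (s in c("male", "female")) {
    expect_identical(t1$incidence(grid$age, grid$year, s),
                     t2$incidence(grid$age, grid$year, s))
    expect_identical(t1$mortality(grid$age, grid$year, s),
                     t2$mortality(grid$age, grid$year, s))
    # default truths live in a realistic incidence range
    expect_true(all(t1$incidence(grid$age, grid$year, s) > 0))
    expect_true(all(t1$incidence(grid$age, grid$year, s) < 0.1))
  }
  t3 <- generate_ground_truth(seed = 5)
  expect_false(identical(t1$incidence(grid$age, grid$year, "male"),
                         t3$incidence(grid$age, grid$year, "male")))
  # zero trend parameter makes incidence year-independent
  t0 <- generate_ground_truth(list(gamma = list(male = 0, female = 0)),
                              seed = 4)
  expect_equal(t0$incidence(50, 2040, "male"), t0$incidence(50, 2015, "male"))
  # inadmissible parameters are named
  expect_error(generate_ground_truth(list(gompertz_b = -1)), "gompertz_b")
  expect_error(generate_ground_truth(
    list(anchor_rates = list(male = rep(-1, 5), female = rep(1, 5) / 1000))),
    "anchor_rates")
  # the incidence trend is flat before the first observed year
  expect_equal(t1$incidence(50, 2012, "male"), t1$incidence(50, 2015, "male"))
})

test_that("sampled estimates have the expected layout, weighting and noise behavior", {
  truth <- generate_ground_truth(seed = 4)
  est <- sample_incidence_estimates(truth, seed = 1)
  expect_equal(nrow(est), 2L * 5L * 7L)
  expect_setequal(unique(est$age_group), standard_age_groups())

  # noise-free weighted estimates equal the person-time-weighted group mean
  est0 <- sample_incidence_estimates(truth, noise_sd = 0)
  ages <- 35:49
  w <- truth$population(ages, 2016, "female")
  manual <- sum(w * truth$incidence(ages, 2016, "female")) / sum(w)
  got <- est0$rate[est0$sex == "female" & est0$age_group == "35-49" &
                   est0$year == 2016]
  expect_equal(got, manual, tolerance = 1e-12)

  # same seed, same draws; different seed, different draws
  expect_identical(sample_incidence_estimates(truth, seed = 9)$rate,
                   sample_incidence_estimates(truth, seed = 9)$rate)
  expect_false(identical(sample_incidence_estimates(truth, seed = 9)$rate,
                         sample_incidence_estimates(truth, seed = 10)$rate))

  # optional pandemic dip only rescales the 2020 rates
  dip <- sample_incidence_estimates(truth, noise_sd = 0, pandemic_dip = 0.8)
  expect_equal(dip$rate[dip$year == 2020], 0.8 * est0$rate[est0$year == 2020])
  expect_equal(dip$rate[dip$year != 2020], est0$rate[est0$year != 2020])
})

test_that("the cohort oracle obeys its closed-form and degenerate limits", {
  # no incidence, no differential mortality: prevalence is constant
  flat <- cohort_microsimulation(0, 0.05, 1, 0.3, 40, 2000, 2020, dt = 0.01)
  expect_equal(flat$prevalence, rep(0.3, nrow(flat)), tolerance = 1e-12)

  # constant incidence, MRR = 1: p = 1 - exp(-i t) within O(dt)
  tr <- cohort_microsimulation(0.02, 0.01, 1, 0, 30, 2000, 2010, dt = 0.001)
  expect_equal(tr$prevalence[nrow(tr)], 1 - exp(-0.2), tolerance = 1e-4)

  # too-large steps are rejected before occupancies can go negative
  expect_error(cohort_microsimulation(0.5, 0.9, 1, 0, 30, 2000, 2010, dt = 5),
               "too large")

  # occupancies stay positive under admissible rates
  set.seed(31)
  for (k in 1:5) {
    tr2 <- cohort_microsimulation(runif(1, 0, 0.1), runif(1, 0, 0.2),
                                  1 + runif(1, 0, 2), runif(1, 0, 0.5),
                                  30, 2000, 2030, dt = 0.005)
    occ <- attr(tr2, "occupancies")
    expect_true(all(occ >= 0))
    expect_true(all(tr2$prevalence >= 0 & tr2$prevalence <= 1))
  }
})

test_that("oracle and characteristic integrator converge toward each other", {
  truth <- generate_ground_truth(seed = 8)
  laws <- truth_laws(truth, "female")
  inc <- rate_surface_from_function(laws$incidence, "female", 18:100, 2010:2040)
  mort <- rate_surface_from_function(laws$mortality, "female", 18:100, 2010:2040)
  sch <- mrr_schedule("female", 2010, 18:100, truth$mrr(18:100, 2010),
                      annual_factor = truth$params$mrr_annual_factor)
  gap <- function(step, dt) {
    a <- integrate_characteristic(0.05, 50, 2010, 2030, inc, mort, sch,
                                  step = step)
    b <- cohort_microsimulation(inc, mort, sch, 0.05, 50, 2010, 2030, dt = dt)
    abs(a$prevalence[nrow(a)] - b$prevalence[nrow(b)])
  }
  coarse <- gap(1, 0.05)
  fine <- gap(0.1, 0.002)
  expect_lt(fine, coarse)
  expect_lt(fine, 1e-3)
})

test_that("oracle-built profiles start at the entry prevalence and rise with age", {
  truth <- generate_ground_truth(seed = 8)
  prof <- oracle_prevalence_profile(truth, 2015, ages = c(18, 30, 50, 70),
                                    dt = 0.01)
  expect_equal(nrow(prof), 8L)
  for (s in c("male", "female")) {
    d <- prof[prof$sex == s, ]
    expect_equal(d$prevalence[1], truth$p18)
    expect_true(all(diff(d$prevalence) > 0))
    expect_true(all(d$prevalence < 0.5))
  }
})

test_that("synthetic input directories are complete and reloadable", {
  dir <- file.path(tempdir(), "idmprev-synth-unit")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_synthetic_inputs(dir, seed = 2, ages = 18:40,
                                  years = 2010:2020, profile_dt = 0.02)
  expect_true(all(file.exists(unlist(paths[c("incidence_estimates",
                                             "prevalence", "mortality",
                                             "mrr", "population",
                                             "config")]))))
  inputs <- load_inputs(dir)
  expect_equal(inputs$ages, 18:40)
  expect_equal(nrow(inputs$estimates), 70L)
  # per-1000 units are converted back to per-1 on load
  expect_lt(max(inputs$estimates$rate), 0.1)
  expect_equal(length(inputs$baseline$male), length(inputs$ages))
  expect_s3_class(inputs$mortality$female, "rate_surface")
  expect_s3_class(inputs$mrr$male, "mrr_schedule")
})
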