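write_lines_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("tables are read, typed and validated with named diagnostics", {
  path <- write_lines_csv(c("sex,age_group,year,rate",
                            "male,18-34,2015,1.2",
                            "male,35-49,2015,4.0",
                            "female,80+,2016,11.0",
                            "female,<18,2016,0.1"))
  tab <- read_rate_table(path, "incidence_estimates")
  expect_equal(nrow(tab), 4L)
  expect_type(tab$rate, "double")

  # per-1000 conversion
  tab1000 <- read_rate_table(path, "incidence_estimates", rate_unit = "per1000")
  expect_equal(tab1000$rate, tab$rate / 1000)
  expect_equal(tab1000$rate[3], 0.011)

  neg <- write_lines_csv(c("sex,age,year,rate", "male,50,2015,-0.1"))
  expect_error(read_rate_table(neg, "mortality"), "rows 1")
  dup <- write_lines_csv(c("sex,age,year,count", "male,50,2015,10",
                           "male,50,2015,12"))
  expect_error(read_rate_table(dup, "population"), "duplicate")
  short <- write_lines_csv(c("sex,year,rate", "male,2015,0.1"))
  expect_error(read_rate_table(short, "mortality"), "age")
  badgrp <- write_lines_csv(c("sex,age_group,year,rate",
                              "male,eighteen,2015,0.1"))
  expect_error(read_rate_table(badgrp, "incidence_estimates"), "unparseable")
  badsex <- write_lines_csv(c("sex,age,year,rate", "m,50,2015,0.1"))
  expect_error(read_rate_table(badsex, "mortality"), "sex")
  badprev <- write_lines_csv(c("sex,age,year,prevalence",
                               "male,50,2015,1.4"))
  expect_error(read_rate_table(badprev, "prevalence"), "above 1")
  expect_error(read_rate_table(path, "incidence_estimates",
                               rate_unit = "bogus"))
  pop <- write_lines_csv(c("sex,age,year,count", "male,50,2015,10"))
  expect_error(read_rate_table(pop, "population", rate_unit = "per1000"),
               "only applies")
})

test_that("write-then-read round-trips tables at full precision", {
  set.seed(21)
  s <- rate_surface("female", 30:34, 2010:2013,
                    matrix(runif(20, 0, 0.09), 5, 4))
  path <- tempfile(fileext = ".csv")
  write_rate_table(surface_to_table(s), path)
  tab <- read_rate_table(path, "mortality")
  s2 <- surface_from_table(tab, "female")
  expect_identical(s2$values, s$values)
})

test_that("counts and crude prevalence follow the population-weighted arithmetic", {
  prev <- prevalence_surface("male", c(60, 61), c(2015, 2016),
                             matrix(c(0.1, 0.2, 0.1, 0.2), 2, 2))
  pop <- data.frame(sex = "male", age = c(60, 61), year = 2015,
                    count = c(1000, 500))
  cc <- counts_from_prevalence(prev, pop, 2015)
  expect_equal(cc$cases, c(100, 100))
  expect_equal(cc$total_cases, 200)
  expect_equal(overall_prevalence(prev, pop, 2015), 200 / 1500)

  pop_eq <- data.frame(sex = "male", age = c(60, 61), year = 2015,
                       count = c(800, 800))
  expect_equal(overall_prevalence(prev, pop_eq, 2015), 0.15)
  pop_one <- data.frame(sex = "male", age = c(60, 61), year = 2015,
                        count = c(0, 700))
  expect_equal(overall_prevalence(prev, pop_one, 2015), 0.2)

  zero <- prevalence_surface("male", c(60, 61), 2015, matrix(0, 2, 1))
  expect_equal(counts_from_prevalence(zero, pop, 2015)$total_cases, 0)
  one <- prevalence_surface("male", c(60, 61), 2015, matrix(1, 2, 1))
  expect_equal(counts_from_prevalence(one, pop, 2015)$cases, pop$count)

  expect_error(counts_from_prevalence(prev, pop, 2030), "not covered")
  expect_error(counts_from_prevalence(prev, pop[0, ], 2015), "no rows")

  # ages above the top grid node pool into the open-ended top group
  pop_top <- data.frame(sex = "male", age = c(60, 61, 75, 90), year = 2015,
                        count = c(1000, 500, 300, 200))
  cc_top <- counts_from_prevalence(prev, pop_top, 2015)
  expect_equal(cc_top$cases, c(100, 0.2 * 1000))
})

test_that("aggregation identity: crude prevalence times population equals cases", {
  set.seed(23)
  ages <- 18:40
  prev <- prevalence_surface("female", ages, 2020,
                             matrix(runif(length(ages), 0, 0.3)))
  pop <- data.frame(sex = "female", age = ages, year = 2020,
                    count = runif(length(ages), 100, 2000))
  cc <- counts_from_prevalence(prev, pop, 2020)
  expect_equal(overall_prevalence(prev, pop, 2020) * cc$total_population,
               cc$total_cases, tolerance = 1e-12)
})

test_that("the constant-prevalence counterfactual responds only to demography", {
  ages <- c(40, 70)
  ref <- list(male = c(0.05, 0.25), female = c(0.05, 0.25))
  years <- 2015:2018
  # population shifts mass toward the high-prevalence age
  pop <- do.call(rbind, lapply(seq_along(years), function(k) {
    data.frame(sex = rep(c("male", "female"), each = 2),
               age = rep(ages, 2), year = years[k],
               count = rep(c(1000 - 100 * (k - 1), 500 + 100 * (k - 1)), 2))
  }))
  res <- constant_prevalence_projection(ref, pop, years, ages = ages)
  tot <- res$totals[res$totals$sex == "total", ]
  expect_true(all(diff(tot$prevalence) > 0))

  # flat reference profile: crude prevalence is that constant, always
  resc <- constant_prevalence_projection(list(male = c(0.1, 0.1),
                                              female = c(0.1, 0.1)),
                                         pop, years, ages = ages)
  expect_equal(resc$totals$prevalence, rep(0.1, nrow(resc$totals)))

  # frozen population: identical totals in every year
  pop_const <- pop
  pop_const$count <- rep(c(1000, 500), length.out = nrow(pop))
  resf <- constant_prevalence_projection(ref, pop_const, years, ages = ages)
  totf <- resf$totals[resf$totals$sex == "total", ]
  expect_equal(max(totf$cases) - min(totf$cases), 0)
})
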