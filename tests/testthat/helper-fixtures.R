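# Shared fixture builders.  Everything is generated in code; no files.

# Constant-valued rate surface over a generous hull.
const_surface <- function(value, sex = "male",
                          ages = c(0, 120), years = c(1990, 2060)) {
  rate_surface(sex, ages, years,
               matrix(value, length(ages), length(years)))
}

# MRR schedule that is constant in age and year (factor 1, no decline).
const_mrr <- function(value, sex = "male", base_year = 1990) {
  mrr_schedule(sex, base_year = base_year, ages = c(0, 120),
               base_mrr = c(value, value), annual_factor = 1)
}

# A small but non-trivial per-sex input set on a reduced grid, for
# pipeline tests that should not pay the full 18:100 x 2010:2040 cost.
small_inputs <- function(truth, ages = 18:70, years = 2010:2030,
                         profile_dt = 0.01) {
  sexes <- stats::setNames(c("male", "female"), c("male", "female"))
  baseline_tab <- oracle_prevalence_profile(truth, min(years), ages = ages,
                                            dt = profile_dt)
  pop <- expand.grid(sex = c("male", "female"), age = ages, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop$count <- mapply(function(a, y, s) truth$population(a, y, s),
                      pop$age, pop$year, pop$sex)
  list(
    baseline = lapply(sexes, function(s) {
      d <- baseline_tab[baseline_tab$sex == s, ]
      d$prevalence[order(d$age)]
    }),
    mortality = lapply(sexes, function(s) {
      rate_surface_from_function(function(a, y) truth$mortality(a, y, s),
                                 s, ages, years)
    }),
    mrr = lapply(sexes, function(s) {
      mrr_schedule(s, base_year = min(years), ages = ages,
                   base_mrr = truth$mrr(ages, min(years)),
                   annual_factor = truth$params$mrr_annual_factor)
    }),
    population = pop,
    ages = ages, years = years
  )
}
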