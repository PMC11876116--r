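---
title: "Projecting chronic disease prevalence with the illness-death model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting chronic disease prevalence with the illness-death model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmprev)
```

## The model and its assumptions

`idmprev` treats a chronic, irreversible condition (its reference
application is diagnosed type 2 diabetes among adults) with the
three-state illness-death model: healthy, ill, dead.  Transitions are
the incidence rate $i(a, t)$, mortality of the healthy $m_0(a, t)$ and
mortality of the ill $m_1(a, t)$, with $a$ age and $t$ calendar time.
The prevalence $p(a, t)$ satisfies

$$\left(\partial_t + \partial_a\right) p
  = (1 - p)\left[\, i - p\,(m_1 - m_0) \,\right].$$

The packaged form never requires $m_0$ or $m_1$ separately: the
mortality difference is rewritten with the identity

$$p\,(m_1 - m_0) \;=\; \frac{p\,(\mathrm{MRR} - 1)\, m}
       {p\,(\mathrm{MRR} - 1) + 1},$$

where $m$ is general-population mortality and
$\mathrm{MRR} = m_1/m_0$ the mortality rate ratio — both routinely
available, unlike $m_0$.  `excess_mortality_term()` implements this
expression exactly; $m_0$ is materialized nowhere in the projection
path (only the cohort oracle recovers it internally, via the same
identity, to step its occupancies).

Model assumptions worth keeping in mind:

* **No remission.**  The ill state is absorbing up to death; the model
  suits diagnosed chronic disease, not conditions people recover from.
* **No migration.**  Cohorts change only through incidence and death.
* **Diagnosed prevalence.**  Whatever ascertainment process generated
  the incidence estimates is inherited by the projection; undiagnosed
  cases are out of scope.

## Numerical integration along characteristics

Along the lines $a - t = \text{const}$ the PDE becomes an ODE, which
`integrate_characteristic()` advances with classical fourth-order
Runge–Kutta.  `project_prevalence_surface()` launches one
characteristic from every age node of the base-year line and one from
the minimum-age node of every later year (entering cohorts), then
collects the values at the rectangular grid nodes.

Numerical choices, and why:

* **RK4, default step 0.1 years.**  The ODE is smooth,
  one-dimensional and cheap; RK4 at $h = 0.1$ puts the discretization
  error at the $10^{-13}$ level against the closed-form constant-rate
  solution (the test suite asserts $\le 10^{-8}$), so the solver
  contributes nothing visible at epidemiological precision.  The
  effective step is $1/\lceil 1/h\rceil$, so integration nodes land
  exactly on calendar years and grid resampling is index arithmetic,
  not interpolation.
* **Age grid 18–100, unit spacing.**  Adults only; the top node
  absorbs the open-ended population group.  Characteristics that
  outrun the grid clamp rate evaluations to the nearest edge.
* **Boundary condition at age 18.**  Entering cohorts carry the
  base-year age-18 prevalence (default truth value 0.004) for all
  years.  Adult-onset prevalence at 18 is near zero for the reference
  condition, so results are insensitive to this choice.
* **Rates between nodes.**  Bilinear interpolation in (age, year),
  clamped to the nearest edge outside the hull.  Kinks of the bilinear
  representation lie on cell borders, which coincide with integration
  substeps, so RK4 retains its order.
* **Clipping.**  Prevalence is clipped to $[0, 1]$ after every step;
  interior RK stages clamp before evaluating the right-hand side.
  The clipping guards against overshoot at coarse steps only — at the
  default step it never activates in a well-posed problem.
* **MRR floor at 1.**  The schedule
  $\max(1, \mathrm{MRR}_0(a) \times 0.98^{\,t - 2010})$ never drops
  below 1: an MRR below 1 would make the condition protective,
  contradicting the survey evidence the baseline profile represents.

## The incidence trend model

Grouped incidence estimates (sex × age group × year) are modeled on
the log scale:

$$\log i \sim \mathrm{ns}(a;\ 4\ \text{knots}) \ast
              \mathrm{ns}(t;\ 1\ \text{interior knot}) \ast \text{sex},$$

a full tensor design (24 columns) fitted by OLS.  Design decisions
that were genuinely open:

* **Knot counting.**  "Four knots" for age is read as two boundary
  plus two interior knots.  With five adult group midpoints this is
  the only identifiable reading: four interior knots would give six
  age-basis functions on five distinct ages, a rank-deficient design.
  Interior knots default to the terciles of the observed midpoints
  (47 and 67 for the standard groups); the year knot sits at the
  median observed year (2018).
* **Representative ages.**  Closed groups enter at their arithmetic
  midpoint; the open-ended "80+" group enters at a configurable
  representative age, default 85 (`midpoint_of()`).  Predictions at
  the oldest ages are mildly sensitive to this default; it can be
  moved via `open_age`.
* **Unweighted OLS.**  The published estimates carry no usable
  uncertainty information, so no weights are applied.
* **Natural-spline extrapolation.**  Beyond the boundary knots the
  log-prediction is linear in age and in year; the trend scenarios
  rely on exactly this behavior to extend the 2015–2021 trend to 2040.
* **Pandemic-year dip.**  The smooth year spline is fitted straight
  through any 2020 under-ascertainment dip; no indicator or correction
  is applied.

## Scenarios

All scenarios share the incidence input up to the last observed year
(2021): predicted values for 2015–2021, and the 2015 prediction for
2010–2014 (the projection starts in 2010, before the first estimate
year).  After 2021 they diverge: `constant_incidence` freezes each
(sex, age) cell at its 2021 value; `trend_until_YYYY` extrapolates the
fitted trend through YYYY and freezes thereafter; freezing is always
per (sex, age) cell.  `constant_prevalence` bypasses the model: the
2015 age profile — obtained by integrating the shared 2010–2015
segment, so its start columns agree exactly with the other scenarios —
is held fixed and only demographic change moves the counts.  MRR
declines 2 % per year from its 2010 profile in every scenario;
mortality follows its input surface.

## The synthetic generator and the cohort oracle

Because the original national inputs are licensed, the package ships a
generator (`generate_ground_truth()`) whose laws emulate their
structure with known ground truth:

* **Incidence**: log-rate = sex-specific age shape + sex-specific
  linear calendar trend (defaults +1.5 %/yr men, +1.0 %/yr women),
  flat before 2015.  The age shape is a linear combination of *the
  same natural-spline basis the trend model uses*, anchored at the
  five group midpoints (defaults rise from ≈0.9/1000 person-years at
  26 to a plateau of ≈11–12/1000 around 70–85).  Keeping the truth in
  the fitted span is deliberate: it makes noise-free recovery exact,
  so the end-to-end check isolates pipeline and integration error
  rather than basis mismatch.  The flat-before-2015 rule mirrors the
  projection's own use of the 2015 prediction for earlier years.
* **Mortality**: Gompertz $a\,e^{0.092\,\text{age}}$ with 1 %/yr
  improvement; ≈0.02/yr at age 70 in 2010.
* **MRR**: piecewise linear from 3.0 (age 30) to 1.3 (age 90) in 2010,
  declining 2 %/yr, floored at 1.
* **Baseline prevalence**: not free — computed by running the cohort
  oracle to the base year, so it is consistent with the generating
  rates and an exact projector should reproduce it.
* **Population**: anchored pyramid (≈68 million adults), aging drift
  0.4 years/year, configurable growth; female surplus above age 60.

Default magnitudes were calibrated once so the 2015 crude adult
prevalence is ≈10 % — the regime of the reference application — and
are not tuned thereafter.  A seed jitters anchors, trends, mortality
level and MRR multiplicatively, producing distinct admissible truths
for property tests.

`cohort_microsimulation()` is the package's independent oracle: an
explicit Euler recursion (default $dt = 0.001$ years) on the *state
occupancies* $H$ and $I$, structurally unrelated to the
prevalence-ODE path.  The two implementations agree within
$3\times10^{-5}$ absolute prevalence across random truths (measured by
`scripts/acceptance.R`; the test bound is $10^{-3}$), and their gap
shrinks as both steps shrink.  Profile reconstruction
(`oracle_prevalence_profile()`) defaults to $dt = 0.0025$, keeping the
Euler error two orders of magnitude below the 1 % scale at which
profiles are compared while holding a full 83-age, two-sex profile to
a few seconds.

Grouped estimates are sampled in two modes.  The default `"weighted"`
mode returns person-time-weighted group means of the true rate —
faithful to how published group estimates arise, and carrying the same
small upward aggregation bias (a few percent in wide young groups,
where the rate is log-convex across 15–17 years of age) that real
midpoint-based fitting inherits.  The `"midpoint"` mode evaluates the
truth at the representative ages; it is the right input for recovery
checks, where estimate construction should not confound pipeline
validation.  The end-to-end recovery check accordingly uses noise-free
midpoint-mode estimates; the aggregation bias itself is quantified by
a dedicated test.

What the generator does *not* emulate: claims-data mechanics
(diagnosis coding, insurer churn), migration, any causal pandemic
mechanism, and sampling uncertainty of the baseline prevalence,
mortality, MRR or population inputs.  Passing tests therefore
demonstrate the correctness of the machinery under known smooth laws,
not the accuracy of any real-world forecast.

## Validation design

The package validates itself along six lines (unit/property suites
plus `scripts/acceptance.R`): published-table arithmetic, closed-form
limit, oracle equivalence, end-to-end recovery, scenario ordering, and
fit unbiasedness.  Two design notes:

* **Summary-table arithmetic.**  Relative changes are computed from
  unrounded start/end values and then rounded half away from zero —
  the order of operations that makes the published reference table
  internally consistent.  Only the 18 cells of that table whose
  printed change agrees with the arithmetic of their printed start/end
  values are asserted exactly; the remainder differ only through the
  table's own rounding of hidden digits.
* **Unbiasedness band.**  Over 200 noisy replicates the per-point
  z-scores of the mean log-scale prediction error are compared against
  a simultaneous threshold, $\Phi^{-1}(1 - 0.025/24) \approx 3.08$,
  with 24 the design rank: a per-point 2-SE band applied at every
  evaluation point simultaneously would reject a true null with
  probability near $1 - 0.95^{24} \approx 0.7$ through multiplicity
  alone.  The grand-mean bias is additionally held within 2 SE.

Problem sizes used by the default validation runs: the reference grid
(ages 18–100, years 2010–2040, RK4 step 0.1), 20 random truths × 3
characteristics for the oracle comparison, and 200 replicates for the
bias study — together about half a minute of compute, chosen so the
whole suite stays comfortably interactive.

## Known limitations

* Forecast quality is bounded by the incidence-trend extrapolation;
  the scenarios bracket, but do not weight, plausible futures.  No
  uncertainty intervals are produced.
* The open-ended age group's representative age (default 85) and the
  entry-age boundary prevalence are conventions, not estimates.
* Grouped-estimate aggregation bias (weighted group mean vs midpoint
  value) propagates into fits on real data at the few-percent level in
  wide, steep age groups; the package measures it but does not correct
  for it.
* The constant-prevalence counterfactual ignores the illness-death
  dynamics by construction and is included for comparability with
  other projection studies, not as a plausible scenario.
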