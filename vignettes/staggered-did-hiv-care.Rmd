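---
title: "Evaluating staggered Medicaid expansion effects on the HIV care continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating staggered Medicaid expansion effects on the HIV care continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivdid)
```

## The evaluation problem

State Medicaid expansion under the ACA rolled out in a staggered fashion:
most adopting states expanded on January 1, 2014, a few in 2015 and 2016,
and the rest not at all during 2012--2017. For people with HIV engaged in
clinical care, this staggered adoption is a quasi-experiment: did expansion
change retention in care, ART receipt, viral suppression, or CD4 count at
entry into care?

`hivdid` implements the full evaluation pipeline: deriving annual
care-continuum indicators from person-level care records, a staggered
difference-in-differences (DID) estimator of the average treatment effect
on the treated (ATT) with not-yet-treated comparison states, three
alternative estimators that relax different assumptions, the standard
sensitivity analyses, and a synthetic cohort generator with known injected
effects so every estimator has a parameter-recovery test surface.

## Outcome definitions and the person-year panel

One row per person per contributed calendar year (2012--2017). A person
contributes from their first to their final clinic visit (or death),
clipped to the window; intermediate years without visits still contribute.

* **Retention in care**: at least 2 primary-care visits in the year
  separated by *strictly more than* 90 days. Assessed only in years after
  the year of entry into care. Because "some pair more than 90 days apart"
  is equivalent to `max(date) - min(date) > 90`, the check is linear-time.
* **ART receipt**: a regimen of 3 or more antiretroviral agents (excluding
  triple-nucleoside regimens) overlapping at least one day of the year,
  among person-years with at least one visit.
* **Viral suppression**: last HIV-1 RNA of the year below 200 copies/mL,
  among person-years with a visit and at least one RNA result. When two
  results share the last date we take the *maximum* (conservative toward
  non-suppression).
* **CD4 at enrollment**: first CD4 count within 6 months of the enrollment
  date. "6 months" is implemented as 182 days with both endpoints included
  (`cd4_window_days`, configurable); the source definitions leave the exact
  day count open, and a one-day shift moves almost no real measurements.

Expansion exposure is coarsened to calendar years: the five states that
expanded after January 1 (AK, IN, LA, MI, NH) are treated as exposed from
January 1 of their expansion year. The bundled policy table reproduces the
published counts -- 26 states expanding in 2014, 3 in 2015, 2 in 2016 --
under the convention that DC expands in the data but is not counted as a
state.

Entry-year exclusion applies only to retention; ART and suppression use
visit-based denominators in every contributed year. Persons enrolled before
2012 contribute person-time but no CD4-at-enrollment row, since the CD4
analysis is restricted to newly enrolled patients.

## The staggered DID estimator

For expansion cohort $g$ (states first exposed in year $g$) and calendar
year $t$, the group-time effect is

$$\mathrm{ATT}(g,t) =
\Big(\bar Y^{g}_{t} - \bar Y^{g}_{b}\Big) -
\frac{1}{n_g}\sum_{i \in g}\big[\hat m_t(X_i) - \hat m_b(X_i)\big],$$

where $b$ is the base period ($g-1$ for post periods; the immediately
preceding year for pre-period placebo cells, the `"varying"` default), and
$\hat m_t$, $\hat m_b$ are outcome regressions fit among the comparison
rows of periods $t$ and $b$. The comparison group at $t$ is the set of
states *not yet expanded by* $t$, excluding cohort $g$ itself. With no
covariates each cell reduces exactly to the 2x2 difference of means. The
panel is treated as repeated cross-sections: person-years are pooled within
group-time cells, matching the annual-indicator structure of the data
(the same person can enter many years, and the state is the cluster for
all inference).

Covariates follow the primary analysis model: Census region, age at
enrollment through a natural cubic spline with 3 knots (placed at the
10th/50th/90th percentiles of age among analysis rows, boundary knots at
the observed range), Black non-Hispanic vs other, and sex. Outcome
regression (rather than a doubly robust construction) keeps the adjustment
exactly aligned with that covariate set; estimation is on the outcome
scale, so binary effects are probability differences. The CD4 analysis
uses newly enrolled persons in 2013--2014 only (data sparsity), with
region coded South vs other, and reduces to a single (g = 2014, t = 2014)
cell on the cells/mm^3 scale.

Cells aggregate by length of exposure $e = t - g$:
$\theta(e) = \sum_g w_g(e)\,\mathrm{ATT}(g, g+e)$ with $w_g(e)$
proportional to cohort size, and the overall effect averages the
post-expansion $\theta(e)$ with weights proportional to the person-years
observed at each exposure length. Person-years (not persons) measure
"size of each exposure group"; both are defensible and the choice is
configurable in spirit -- the weights are returned so any re-weighting can
be checked by hand.

### Inference

Each cell estimate carries per-state influence contributions; aggregation
is linear in them. A multiplier bootstrap draws Rademacher signs per state
per replication (999 by default) and perturbs every quantity by the
sign-weighted sum of its cluster contributions; CIs are symmetric with the
0.95 quantile of the absolute perturbations as critical value.

Three small-sample points matter at this design's scale. First, cells for
the 2015 and 2016 cohorts rest on only 3 and 2 treated states; centering
within the treated side with $G$ clusters shrinks its apparent variance by
$(G-1)/G$, so treated-side contributions are rescaled by $\sqrt{G/(G-1)}$
-- the standard cluster correction, material only for the tiny cohorts.
Second, the comparison-regression influence terms use CR3-style
leave-one-cluster-out residuals: in cells where the comparison pool has
shrunk, a region dummy can be identified by a single comparison state,
absorb that state's entire cluster effect, and leave ordinary residuals
that vanish at the cluster level -- the bootstrap would then see none of
that coefficient's variance. LOO residuals restore it (at the price of
mild conservatism), leaving point estimates untouched. Third, the joint
pre-trends test does not invert the
estimated covariance of the pre-period cells (poorly estimated with so few
treated clusters); instead it uses a fixed, size-weighted quadratic form
$\sum_j w_j \hat\theta_j^2$ whose null distribution is read off the same
bootstrap draws. Well-estimated cells dominate both size and power, and
the reference distribution reflects the true cluster structure rather than
a chi-square asymptote. A plain Wald chi-square utility
(`pretrends_wald()`) is also exported for covariance inputs from other
sources.

## Alternative estimators

* **Comparative interrupted time series (GEE)** (`fit_its_gee()`): the
  two-period (2013/2014) model $g(E[Y]) = \beta_0 + \beta_1\,\mathrm{exp} +
  \beta_2\,\mathrm{post} + \beta_3\,\mathrm{exp}\times\mathrm{post} +
  X\gamma$ with independent working correlation. With working independence
  the estimating-equation solution coincides with ordinary ML, so the fit
  is a `glm` and the GEE robust variance is the cluster sandwich
  (clustered on person -- the repeated annual measures; the textbook GEE
  sandwich, without finite-sample degrees-of-freedom adjustment). Binary
  outcomes report the ratio of odds ratios $e^{\beta_3}$; CD4 reports
  $\beta_3$ directly.
* **Propensity-score-weighted DID** (`fit_propensity()`,
  `ps_weighted_did()`): logistic regression of expansion-state residence on
  age, race/ethnicity and sex, fully interacted. Age enters as quintiles so
  the design is saturated and fitted scores equal empirical cell
  proportions -- ATT weights (treated 1, comparison $p/(1-p)$) then balance
  the covariate cells exactly. The "matchable set" is implemented as
  common-support trimming: rows outside the overlap of the group-wise score
  ranges are dropped from both groups. The outcome model is a weighted
  two-period regression with an expansion-by-period term, with and without
  region. Optional weight truncation (99th percentile) is off by default.
* **Ridge-augmented synthetic control** (`scm_estimate()`): for each
  expansion state, donor weights solve the simplex-constrained least
  squares $\min_w \|y_{pre} - D_{pre} w\|^2$ (an exact active-set solver
  written for this package -- small problems, deterministic); the
  counterfactual adds a ridge outcome-model correction
  $(x_{pre} - D_{pre}w)'\hat\beta_t(\lambda)$, with $\hat\beta_t$ the ridge
  regression of donor post-year outcomes on donor pre-period vectors and
  $\lambda$ chosen by leave-one-pre-period-out cross-validation on a
  log-spaced grid (ties to the smallest; degenerate series flagged at the
  grid minimum). Donors are states untreated throughout the treated state's
  horizon. With staggered adoption each treated state is fit separately and
  effects are averaged on event time with size weights; the CI is a
  jackknife over treated states (the augmentation uses lagged outcomes
  only, matching the state-level-summaries design; conformal placebo
  inference would be the natural extension). With perfect pre-fit, or as
  $\lambda \to \infty$, the estimator reduces to classic SCM.

These estimators target subtly different estimands (individual-level ATT
in 2014 for ITS and PS; a state-level average for SCM), which is exactly
why they are useful as sensitivity analyses for the primary staggered DID.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a large multi-state clinical
HIV cohort: 50 states + DC with the bundled expansion schedule, 200
persons per state by default, enrollment spread over 2010--2017, geometric
dropout (8%/year), and covariates (age, sex, race/ethnicity with a South
tilt) whose defaults make the *derived* panel match observed levels --
retention near 0.74, ART near 0.97, suppression near 0.85, about 11% of
visit-years without an RNA result, and CD4 at enrollment generated on the
square-root scale (normal, then squared) centered to a median near 543
cells/mm^3. A square-root-normal cannot match the reported IQR (327--718)
exactly -- the real distribution is more right-skewed -- so the location
is prioritized; this is a known, documented approximation.

Binary outcomes are drawn from logistic models with state random
intercepts (inducing the within-state correlation the clustered bootstrap
must handle), a shared secular trend (parallel trends hold by
construction), and the configured treatment effect, applied either on the
probability scale (`att_scale = "response"`, the DID estimand directly) or
the logit scale. Records are then generated *consistently with the drawn
indicators*: a retained person-year gets visits >200 days apart, a
non-retained one gets all visits inside an 86-day window; an ART year gets
a qualifying 3-agent span while non-ART years get nothing, a
triple-nucleoside span, or a 2-agent span; the last RNA of the year sits
below or above 200 copies/mL according to the suppression draw. Injected
effects therefore propagate through the full derivation pipeline, not just
through a shortcut outcome column. `truth_on_probability_scale()` returns
the realized probability-scale ATT (for logit-scale effects, by averaging
inverse-link differences over treated person-years).

Visit counts average about 2.5 per person-year (every contributed year has
at least one visit, so denominators behave as configured); visit dates are
otherwise uniform -- adequate to exercise the 90-day rule, though real
visit patterns are burstier. One master seed streams into per-table
substreams, so adding a table does not perturb earlier draws and identical
(config, seed) pairs are byte-identical.

A `pretrend_violation` switch (off by default) adds a differential drift
of 1 logit/year (on the order of 13--19 percentage points/year at these
prevalences) to eventual expansion states. This is deliberately a gross,
unmistakable violation: the switch exists to demonstrate that the
pre-trends diagnostic rejects when parallel trends fail clearly, not to
probe its detection threshold. With varying-base placebo cells each
pre-period contrast sees only one year of differential drift, so subtle
drifts (a point or two per year) sit below any test's detection floor at
this design's scale -- a caveat for applied interpretation, stated here
rather than hidden.

What passing tests on this generator do **not** show about real data: the
generator has no differential selection into care, no migration between
states, no insurance-status dynamics, no RWHAP safety-net interactions,
and homogeneous treatment effects. Parameter recovery here validates the
estimators' statistical machinery under the identification assumptions,
not the assumptions themselves.

## Numerical choices and degenerate inputs

* Calendar years are closed intervals; dates are handled as integer day
  offsets.
* Strictness at boundaries: the 90-day rule is strict (`> 90`); the
  suppression threshold is strict (`< 200`); the CD4 window is closed at
  both ends.
* Rank-deficient outcome regressions in a (g, t) cell (e.g., an empty
  covariate cell among comparators) drop the deficient directions and warn
  with row counts.
* Cells whose treated side has fewer than 2 states are estimated but
  flagged; panels with fewer than 2 treated or 2 comparison states refuse
  inference outright.
* The active-set QP clips weights below ~1e-10 to zero and renormalizes;
  feasibility (`|sum(w) - 1| < 1e-8`, `w >= 0`) is asserted in tests
  against a brute-force simplex grid oracle.
* Bootstrap and simulation problem sizes in the test suite: 100 seeds for
  parameter recovery and 200 (null) + 60 (violation) seeds for pre-trends
  calibration at the default scale of 51 states x 200 persons, with
  499-replication bootstraps inside Monte-Carlo loops and 999 elsewhere.
  These sizes give binomial standard errors around 1.5--2.5 percentage
  points on coverage and rejection rates, adequate for the bands asserted.

## Known limitations

* The paper-scale headline numbers (e.g., CD4 DID = 93.5 cells/mm^3) come
  from confidential cohort data; the package validates estimator behavior
  on synthetic cohorts with known truth instead.
* No doubly robust DID flavor, no simultaneous confidence bands, no
  conformal SCM inference (all natural extension hooks).
* No multiplicity correction across outcomes (none is applied in the
  design this package implements; reports should say so).
* The GEE cluster unit is the person; with state-level exposure one could
  argue for state clustering, but the comparative ITS is a sensitivity
  analysis and the primary DID already clusters on state.
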