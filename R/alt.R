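#' Comparative interrupted time series via estimating equations
#'
#' Fits the two-period (2013 pre, 2014 post) comparative interrupted time
#' series model \eqn{g(E[Y]) = \beta_0 + \beta_1 \mathrm{expansion} + \beta_2
#' \mathrm{post} + \beta_3 \mathrm{expansion \times post} + X\gamma} with an
#' independent working correlation structure and a cluster-robust (sandwich)
#' variance clustered on person. With independence working correlation the
#' estimating-equation point estimates coincide with ordinary ML, so the fit
#' is computed by [stats::glm()] and the working-independence GEE variance by
#' [sandwich::vcovCL()].
#'
#' For the binomial family the reported effect is the ratio of odds ratios
#' \eqn{\exp(\beta_3)} with a CI on the exponentiated scale; for the gaussian
#' family it is \eqn{\beta_3} itself (a mean-difference DID, used for CD4).
#'
#' @param data person-year rows (or enrollment-CD4 rows) containing the
#'   outcome, a `state`-based exposure, and covariates.
#' @param outcome name of the outcome column.
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity).
#' @param policy policy table used to define the expansion-state indicator
#'   (expansion year 2014 vs not-yet/never by 2014).
#' @param time_col column giving the period (year); `years[1]` is pre,
#'   `years[2]` post.
#' @param years the two analysis years, default `c(2013, 2014)`.
#' @param covariates character vector among `c("region", "region_south",
#'   "age", "race", "sex")` (same coding as [did_att()]).
#' @param cluster column to cluster the sandwich variance on (default
#'   `"person_id"`).
#' @return list with `estimate` (ROR or mean-difference DID), `ci_lo`,
#'   `ci_hi`, `se` (link scale), `beta3`, `family`, `n`, `converged`, and
#'   the underlying `fit`.
#' @export
fit_its_gee <- function(data, outcome, family = c("binomial", "gaussian"),
                        policy, time_col = "year", years = c(2013L, 2014L),
                        covariates = c("region", "age", "race", "sex"),
                        cluster = "person_id") {
  family <- match.arg(family)
  d <- as.data.frame(data)
  d <- d[d[[time_col]] %in% years, ]
  if (!"expansion_year" %in% names(d)) {
    if (!"expansion_year" %in% names(policy)) {
      policy <- coarsen_expansion(policy)
    }
    d$expansion_year <- policy$expansion_year[match(d$state, policy$state)]
  }
  d$.y <- d[[outcome]]
  d <- d[!is.na(d$.y), ]
  d$expansion <- as.integer(!is.na(d$expansion_year) &
                              d$expansion_year <= years[2])
  d$post <- as.integer(d[[time_col]] == years[2])
  if (length(unique(d$expansion)) < 2 || length(unique(d$post)) < 2) {
    stop("both exposure groups and both periods are required")
  }
  rhs <- c("expansion * post", its_covariate_terms(d, covariates))
  f <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  d$region <- if ("region" %in% names(d)) {
    factor(d$region, levels = c("Northeast", "South", "Midwest", "West"))
  } else d$region
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  fit <- stats::glm(f, family = fam, data = d)
  separation <- family == "binomial" && !fit$converged
  V <- sandwich::vcovCL(fit, cluster = d[[cluster]], type = "HC0", cadjust = FALSE)
  b3 <- stats::coef(fit)[["expansion:post"]]
  se3 <- sqrt(V["expansion:post", "expansion:post"])
  z <- stats::qnorm(0.975)
  if (family == "binomial") {
    out <- list(estimate = exp(b3), ci_lo = exp(b3 - z * se3),
                ci_hi = exp(b3 + z * se3))
  } else {
    out <- list(estimate = b3, ci_lo = b3 - z * se3, ci_hi = b3 + z * se3)
  }
  c(out, list(se = se3, beta3 = b3, family = family, n = nrow(d),
              converged = !separation, fit = fit))
}

its_covariate_terms <- function(d, covariates) {
  terms <- character(0)
  if ("region" %in% covariates) terms <- c(terms, "region")
  if ("region_south" %in% covariates) terms <- c(terms, "region_south")
  if ("age" %in% covariates) {
    age <- d$age_at_enrollment
    kn <- unique(stats::quantile(age, c(0.1, 0.5, 0.9), names = FALSE))
    bk <- range(age)
    kn <- kn[kn > bk[1] & kn < bk[2]]
    terms <- c(terms, if (length(kn))
      sprintf("splines::ns(age_at_enrollment, knots = c(%s), Boundary.knots = c(%s))",
              paste(kn, collapse = ","), paste(bk, collapse = ",")) else
        "age_at_enrollment")
  }
  if ("race" %in% covariates) terms <- c(terms, "race_black_nh")
  if ("sex" %in% covariates) terms <- c(terms, "sex")
  terms
}

#' Propensity scores for expansion-state residence
#'
#' Logistic regression of residence in a 2014 expansion state on age,
#' race/ethnicity and sex with all variables interacted. Age enters as a
#' 5-level categorical (quintiles) so the fully interacted design is
#' saturated: fitted scores then equal empirical cell proportions exactly,
#' and ATT weighting balances the covariate cells exactly. A continuous-age
#' alternative is available via `age_form = "continuous"`.
#'
#' Rows with missing covariates are excluded (and counted); empty covariate
#' cells fall back to a pooled (main-effects) fit for those rows, flagged in
#' the result.
#'
#' @param rows data.frame with `age_at_enrollment`, `race_eth` (or
#'   `race_black_nh`), `sex`, and a `treated` indicator (expansion-state
#'   residence), e.g. built by [ps_analysis_set()].
#' @param age_form `"quintile"` (default) or `"continuous"`.
#' @return list with `score` (per-row fitted probability, in (0,1)),
#'   `n_excluded_missing`, `pooled_fallback` (logical flag), and `fit`.
#' @export
fit_propensity <- function(rows, age_form = c("quintile", "continuous")) {
  age_form <- match.arg(age_form)
  d <- as.data.frame(rows)
  stopifnot("treated" %in% names(d))
  race_col <- if ("race_eth" %in% names(d)) "race_eth" else "race_black_nh"
  need <- c("age_at_enrollment", race_col, "sex")
  complete <- stats::complete.cases(d[, need])
  n_excl <- sum(!complete)
  d <- d[complete, ]
  if (age_form == "quintile") {
    qs <- unique(stats::quantile(d$age_at_enrollment,
                                 probs = seq(0, 1, 0.2), names = FALSE))
    d$.age <- if (length(qs) < 2) factor("all") else
      cut(d$age_at_enrollment, breaks = qs, include.lowest = TRUE)
  } else {
    d$.age <- d$age_at_enrollment
  }
  d$.race <- factor(d[[race_col]])
  d$.sex <- factor(d$sex)
  ## constant covariates carry no information; keep only multi-level terms
  ## so the fully interacted design stays estimable
  keep <- c(".age", ".race", ".sex")[vapply(
    d[c(".age", ".race", ".sex")],
    function(x) length(unique(x)) > 1, logical(1))]
  f <- if (length(keep)) {
    stats::as.formula(paste("treated ~", paste(keep, collapse = " * ")))
  } else treated ~ 1
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = d))
  score <- as.numeric(stats::predict(fit, type = "response"))
  pooled <- FALSE
  if (anyNA(score) || anyNA(stats::coef(fit))) {
    bad <- is.na(score)
    if (any(bad)) {
      pooled <- TRUE
      fit0 <- suppressWarnings(stats::glm(treated ~ .age + .race + .sex,
                                          family = stats::binomial(),
                                          data = d))
      score[bad] <- as.numeric(stats::predict(fit0, type = "response"))[bad]
    }
  }
  eps <- 1e-6
  score <- pmin(pmax(score, eps), 1 - eps)
  list(score = score, n_excluded_missing = n_excl,
       pooled_fallback = pooled, fit = fit, rows = d)
}

#' Propensity-score-weighted difference-in-differences
#'
#' Weighted regression of the outcome on expansion-state residence, period
#' (2013 vs 2014) and their interaction -- plus region when configured --
#' using ATT weights (treated rows weight 1, comparison rows
#' \eqn{p/(1-p)}) on the common-support ("matchable") set. Rows whose score
#' falls outside the overlap of the group-wise score ranges are trimmed from
#' both groups. Binary outcomes use a logistic link and report the
#' expansion-by-period odds ratio; CD4 uses the identity link and reports the
#' mean difference. Robust (sandwich) CIs clustered on person.
#'
#' @param rows analysis rows with `treated`, `post`, outcome column, and
#'   covariates (see [ps_analysis_set()]).
#' @param scores per-row propensity scores aligned with `rows`.
#' @param outcome outcome column name.
#' @param family `"binomial"` or `"gaussian"`.
#' @param include_region adjust for 4-level region (default FALSE).
#' @param truncate_weights optional upper quantile at which comparison
#'   weights are truncated (e.g. 0.99); `NULL` (default) = off.
#' @param cluster cluster column for the sandwich variance.
#' @return list with `estimate` (OR or mean difference), `ci_lo`, `ci_hi`,
#'   `beta3`, `se`, `n_treated`, `n_comparison`, `n_trimmed`, `balance`
#'   (post-weighting standardized mean differences), and `fit`.
#' @export
ps_weighted_did <- function(rows, scores, outcome,
                            family = c("binomial", "gaussian"),
                            include_region = FALSE,
                            truncate_weights = NULL,
                            cluster = "person_id") {
  family <- match.arg(family)
  d <- as.data.frame(rows)
  stopifnot(nrow(d) == length(scores))
  d$.score <- scores
  ## common support: overlap of group-wise [min, max]
  lo <- max(min(d$.score[d$treated == 1]), min(d$.score[d$treated == 0]))
  hi <- min(max(d$.score[d$treated == 1]), max(d$.score[d$treated == 0]))
  keep <- d$.score >= lo & d$.score <= hi
  n_trim <- sum(!keep)
  d <- d[keep, ]
  if (!any(d$treated == 1) || !any(d$treated == 0)) {
    stop("common-support trimming removed an entire exposure group")
  }
  d$.w <- ifelse(d$treated == 1, 1, d$.score / (1 - d$.score))
  if (!is.null(truncate_weights)) {
    cap <- stats::quantile(d$.w[d$treated == 0], truncate_weights)
    d$.w <- pmin(d$.w, cap)
  }
  d$.y <- d[[outcome]]
  d <- d[!is.na(d$.y), ]
  rhs <- "treated * post"
  if (include_region) {
    d$region <- factor(d$region, levels = c("Northeast", "South", "Midwest",
                                            "West"))
    rhs <- paste(rhs, "+ region")
  }
  f <- stats::as.formula(paste(".y ~", rhs))
  fam <- if (family == "binomial") stats::quasibinomial() else
    stats::gaussian()
  fit <- stats::glm(f, family = fam, data = d, weights = d$.w)
  V <- sandwich::vcovCL(fit, cluster = d[[cluster]], type = "HC0", cadjust = FALSE)
  b3 <- stats::coef(fit)[["treated:post"]]
  se3 <- sqrt(V["treated:post", "treated:post"])
  z <- stats::qnorm(0.975)
  est <- if (family == "binomial") {
    list(estimate = exp(b3), ci_lo = exp(b3 - z * se3),
         ci_hi = exp(b3 + z * se3))
  } else {
    list(estimate = b3, ci_lo = b3 - z * se3, ci_hi = b3 + z * se3)
  }
  c(est, list(beta3 = b3, se = se3, family = family,
              n_treated = sum(d$treated == 1),
              n_comparison = sum(d$treated == 0),
              n_trimmed = n_trim,
              balance = ps_balance(d), fit = fit))
}

## post-weighting standardized mean differences for the PS covariates
ps_balance <- function(d) {
  vars <- list(age = d$age_at_enrollment,
               black = if ("race_black_nh" %in% names(d)) d$race_black_nh
                       else as.integer(d$race_eth == "black_nh"),
               female = as.integer(d$sex == "female"))
  vapply(vars, function(v) {
    t1 <- d$treated == 1
    m1 <- stats::weighted.mean(v[t1], d$.w[t1])
    m0 <- stats::weighted.mean(v[!t1], d$.w[!t1])
    s <- sqrt((stats::var(v[t1]) + stats::var(v[!t1])) / 2)
    if (s == 0) 0 else abs(m1 - m0) / s
  }, numeric(1))
}

#' Assemble the two-period analysis set for the PS and ITS estimators
#'
#' Restricts the person-year panel (or enrollment-CD4 table) to the
#' 2013-2014 window, defines `treated` (residence in a state that expanded
#' by 2014) and `post` (year 2014), and keeps rows in the outcome
#' denominator.
#'
#' @param panel person-year panel or enrollment-CD4 table.
#' @param outcome `"retention"`, `"art"`, `"vs"`, or `"cd4"`.
#' @param years pre/post years, default `c(2013, 2014)`.
#' @return data.frame with `.y` available under the outcome's column name,
#'   `treated`, `post`, covariates, and `person_id`.
#' @export
ps_analysis_set <- function(panel, outcome = c("retention", "art", "vs",
                                               "cd4"),
                            years = c(2013L, 2014L)) {
  outcome <- match.arg(outcome)
  d <- as.data.frame(panel)
  if (outcome == "cd4") {
    d$year <- d$enrollment_year
    d <- d[!is.na(d$cd4_at_enrollment), ]
  } else {
    ocol <- c(retention = "retained", art = "on_art", vs = "suppressed")
    dcol <- c(retention = "in_retention_denominator",
              art = "in_art_denominator", vs = "in_vs_denominator")
    d <- d[d[[dcol[[outcome]]]] == 1 & !is.na(d[[ocol[[outcome]]]]), ]
  }
  d <- d[d$year %in% years, ]
  d$treated <- as.integer(!is.na(d$expansion_year) &
                            d$expansion_year <= years[2])
  d$post <- as.integer(d$year == years[2])
  d
}
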