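#' Configuration for the synthetic cohort generator
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate the structure of a large multi-state HIV clinical cohort observed
#' 2012-2017 under staggered state Medicaid expansion: individuals nested in
#' the 50 states + DC (bundled policy table), annual binary care-continuum
#' outcomes with prevalences near observed levels (retention ~0.74, ART
#' ~0.97, suppression ~0.85), a CD4-at-enrollment distribution generated on
#' the square-root scale and calibrated to median ~543 (IQR ~327-718)
#' cells/mm^3, state-level random intercepts (within-state correlation), a
#' shared secular trend, and configurable injected treatment effects.
#'
#' @param persons_per_state persons simulated per jurisdiction (default 200).
#' @param policy policy table; default the bundled [default_policy()]. Supply
#'   a subset for small experiments, or use `n_states` +
#'   `expansion_distribution` to draw a random policy.
#' @param n_states if `policy` is `NULL` and `n_states < 51`, a policy with
#'   `n_states` jurisdictions is sampled with expansion-year counts given by
#'   `expansion_distribution`.
#' @param expansion_distribution named counts for `"2014"`, `"2015"`,
#'   `"2016"`, `"never"`; must sum to `n_states`.
#' @param window study window, default `c(2012, 2017)`.
#' @param enrollment_years range of enrollment years (default `c(2010,
#'   2017)`; enrollments before the window contribute person-time but no
#'   CD4-at-enrollment row).
#' @param baseline_logit named intercepts (logit scale) for `retention`,
#'   `art`, `vs`; defaults calibrated so marginal prevalences match the
#'   levels above.
#' @param att named list of injected treatment effects for `retention`,
#'   `art`, `vs` (probability or logit scale per `att_scale`) and `cd4`
#'   (cells/mm^3); each may be a vector over post-expansion event times
#'   (recycled beyond its length).
#' @param att_scale `"response"` (probability-scale additive effects, the
#'   estimand the DID module targets) or `"link"` (logit-scale shifts).
#' @param state_sd named logit-scale SDs of state random intercepts.
#' @param trend named logit-scale secular drift per calendar year, shared by
#'   all states (parallel trends hold by construction).
#' @param pretrend_violation logical; when `TRUE`, eventual expansion states
#'   receive an additional differential logit-scale drift of
#'   `violation_drift` per year, violating parallel trends (used to show the
#'   pre-trends test has power). Default `FALSE`.
#' @param violation_drift logit/year differential drift when the violation
#'   switch is on.
#' @param dropout annual probability that follow-up ends after a given year.
#' @param prob_rna probability a person-year with a visit has an RNA
#'   measurement (the suppression denominator).
#' @param prob_cd4_lab probability a new enrollee has a CD4 measurement
#'   within the enrollment window.
#' @param cd4_mean_sqrt,cd4_sd_sqrt,cd4_state_sd,cd4_south_effect,cd4_trend
#'   CD4 generation parameters on the square-root scale.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(persons_per_state = 200,
                       policy = NULL,
                       n_states = 51,
                       expansion_distribution = NULL,
                       window = c(2012L, 2017L),
                       enrollment_years = c(2010L, 2017L),
                       baseline_logit = c(retention = 1.16, art = 3.75,
                                          vs = 1.90),
                       att = list(retention = 0, art = 0, vs = 0, cd4 = 0),
                       att_scale = c("response", "link"),
                       state_sd = c(retention = 0.25, art = 0.30, vs = 0.30),
                       trend = c(retention = 0.00, art = 0.04, vs = 0.08),
                       pretrend_violation = FALSE,
                       violation_drift = 1.0,
                       dropout = 0.08,
                       prob_rna = 0.89,
                       prob_cd4_lab = 0.90,
                       cd4_mean_sqrt = 23.3,
                       cd4_sd_sqrt = 6.46,
                       cd4_state_sd = 1.0,
                       cd4_south_effect = -1.2,
                       cd4_trend = 0.15) {
  att_scale <- match.arg(att_scale)
  stopifnot(persons_per_state >= 1, n_states >= 2)
  if (!is.null(expansion_distribution)) {
    if (sum(expansion_distribution) > n_states) {
      stop("infeasible config: expansion_distribution implies more states (",
           sum(expansion_distribution), ") than n_states (", n_states, ")")
    }
  }
  cfg <- list(persons_per_state = persons_per_state, policy = policy,
              n_states = n_states,
              expansion_distribution = expansion_distribution,
              window = as.integer(window),
              enrollment_years = as.integer(enrollment_years),
              baseline_logit = baseline_logit, att = att,
              att_scale = att_scale, state_sd = state_sd, trend = trend,
              pretrend_violation = isTRUE(pretrend_violation),
              violation_drift = violation_drift, dropout = dropout,
              prob_rna = prob_rna, prob_cd4_lab = prob_cd4_lab,
              cd4_mean_sqrt = cd4_mean_sqrt, cd4_sd_sqrt = cd4_sd_sqrt,
              cd4_state_sd = cd4_state_sd,
              cd4_south_effect = cd4_south_effect, cd4_trend = cd4_trend,
              ## fixed covariate effects (logit scale) shared by defaults
              race_effect = c(retention = -0.15, art = -0.20, vs = -0.35),
              sex_effect = c(retention = -0.05, art = -0.10, vs = -0.10),
              age_effect = c(retention = 0.15, art = 0.20, vs = 0.15),
              region_effect = list(
                retention = c(Northeast = 0.10, South = -0.10, Midwest = 0,
                              West = 0.05),
                art = c(Northeast = 0.05, South = -0.05, Midwest = 0,
                        West = 0.05),
                vs = c(Northeast = 0.10, South = -0.15, Midwest = 0,
                       West = 0.10)))
  class(cfg) <- "sim_config"
  cfg
}

resolve_policy <- function(cfg, seed) {
  if (!is.null(cfg$policy)) {
    pol <- cfg$policy
    if (!"expansion_year" %in% names(pol)) pol <- coarsen_expansion(pol)
    return(pol)
  }
  if (cfg$n_states >= 51 && is.null(cfg$expansion_distribution)) {
    return(default_policy())
  }
  dist <- cfg$expansion_distribution %||%
    c("2014" = round(cfg$n_states * 27 / 51),
      "2015" = max(1, round(cfg$n_states * 3 / 51)),
      "2016" = max(1, round(cfg$n_states * 2 / 51)))
  dist <- dist[setdiff(names(dist), "never")]
  set.seed(substream_seed(seed, 17L))
  pol <- default_policy()
  pol <- pol[sample.int(nrow(pol), cfg$n_states), ]
  yrs <- rep(NA_integer_, cfg$n_states)
  k <- 0
  for (nm in names(dist)) {
    if (dist[[nm]] > 0) {
      yrs[seq.int(k + 1, k + dist[[nm]])] <- as.integer(nm)
      k <- k + dist[[nm]]
    }
  }
  pol$expansion_year <- yrs
  pol$expansion_date <- as.Date(ifelse(is.na(yrs), NA,
                                       paste0(yrs, "-01-01")))
  rownames(pol) <- NULL
  pol
}

att_at_event <- function(att_vec, e) {
  att_vec <- as.numeric(att_vec)
  att_vec[pmin(e + 1L, length(att_vec))]
}

#' Generate a synthetic cohort with known treatment effects
#'
#' Generates the five input tables consumed by [build_panel()] (persons,
#' visits, regimens, labs, policy) plus a `truth` object recording the
#' injected effects, so every estimator in the package has a
#' parameter-recovery test surface. Identical `(config, seed)` yield
#' identical outputs; the master seed is streamed into per-table substreams
#' so adding one table does not perturb earlier draws.
#'
#' Binary outcomes are drawn per person-year from a logistic model with
#' covariate effects, a state random intercept, a shared secular trend, and
#' the configured treatment effect; visit dates, regimen spans and RNA
#' results are then generated *consistently with the drawn indicator* (e.g.,
#' a retained person-year receives visits more than 90 days apart), so the
#' derived panel reproduces the modeled outcomes exactly and injected effects
#' propagate through the full derivation pipeline.
#'
#' @param config a [sim_config()] object.
#' @param seed integer master seed.
#' @return list with `persons`, `visits`, `regimens`, `labs`, `policy`
#'   (data.frames) and `truth` (class `sim_truth`): configured and realized
#'   effects, state random intercepts, expansion assignments.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  cfg <- config
  pol <- resolve_policy(cfg, seed)
  w0 <- cfg$window[1]; w1 <- cfg$window[2]

  ## ---- persons ----
  set.seed(substream_seed(seed, 1L))
  ns <- nrow(pol)
  np <- ns * cfg$persons_per_state
  pe <- data.table::data.table(
    person_id = sprintf("P%06d", seq_len(np)),
    state = rep(pol$state, each = cfg$persons_per_state))
  pe <- merge(pe, data.table::as.data.table(
    pol[, c("state", "region", "expansion_year")]), by = "state")
  data.table::setorder(pe, person_id)
  pe[, sex := ifelse(runif(np) < 0.16, "female", "male")]
  p_black <- 0.34 + 0.18 * (pe$region == "South")
  u <- runif(np)
  pe[, race_eth := ifelse(u < p_black, "black_nh",
                    ifelse(u < p_black + 0.37, "white_nh",
                      ifelse(u < p_black + 0.51, "hispanic", "other_unknown")))]
  age <- pmin(pmax(round(rnorm(np, 45, 12)), 18), 80)
  ey <- sample(seq.int(cfg$enrollment_years[1], cfg$enrollment_years[2]),
               np, replace = TRUE)
  eday <- sample.int(334, np, replace = TRUE)  # enroll Jan-Nov
  pe[, `:=`(age_at_enrollment = age, enrollment_year = ey,
            birth_year = ey - age,
            enrollment_date = year_date(ey) + eday - 1L)]
  dur <- rgeom(np, cfg$dropout)
  pe[, last_year := pmin(enrollment_year + dur, w1)]
  pe[, death_date := as.Date(NA)]
  dies <- runif(np) < 0.015
  pe[dies, death_date := year_date(last_year, "12-31")]

  ## state random intercepts
  re <- data.table::data.table(
    state = pol$state,
    re_retention = rnorm(ns, 0, cfg$state_sd["retention"]),
    re_art = rnorm(ns, 0, cfg$state_sd["art"]),
    re_vs = rnorm(ns, 0, cfg$state_sd["vs"]),
    re_cd4 = rnorm(ns, 0, cfg$cd4_state_sd))

  ## ---- person-year scaffold with outcome probabilities ----
  set.seed(substream_seed(seed, 2L))
  n_yr <- pe$last_year - pe$enrollment_year + 1L
  py <- pe[rep(seq_len(np), n_yr),
           .(person_id, state, region, expansion_year, sex, race_eth,
             age_at_enrollment, enrollment_year)]
  py[, year := sequence(n_yr, from = pe$enrollment_year)]
  py <- merge(py, re, by = "state")
  data.table::setorder(py, person_id, year)
  py[, is_entry_year := year == enrollment_year]
  py[, event_time := year - expansion_year]
  py[, treated := as.integer(!is.na(expansion_year) & year >= expansion_year)]
  drift <- if (cfg$pretrend_violation) cfg$violation_drift else 0

  eta_for <- function(oc, re_col) {
    cfg$baseline_logit[[oc]] +
      cfg$region_effect[[oc]][py$region] +
      cfg$race_effect[[oc]] * (py$race_eth == "black_nh") +
      cfg$sex_effect[[oc]] * (py$sex == "female") +
      cfg$age_effect[[oc]] * (py$age_at_enrollment - 45) / 10 +
      py[[re_col]] +
      cfg$trend[[oc]] * (py$year - w0) +
      drift * (!is.na(py$expansion_year)) * (py$year - w0)
  }
  apply_att <- function(eta, oc) {
    p0 <- expit(eta)
    delta <- numeric(nrow(py))
    tr <- py$treated == 1L
    if (any(tr)) {
      delta[tr] <- att_at_event(cfg$att[[oc]], py$event_time[tr])
    }
    if (cfg$att_scale == "response") {
      p1 <- clip_prob(p0 + delta)
    } else {
      p1 <- expit(eta + delta)
    }
    list(p0 = p0, p1 = p1)
  }
  pr <- apply_att(eta_for("retention", "re_retention"), "retention")
  pa <- apply_att(eta_for("art", "re_art"), "art")
  pv <- apply_att(eta_for("vs", "re_vs"), "vs")
  py[, `:=`(p_ret0 = pr$p0, p_ret = pr$p1,
            p_art0 = pa$p0, p_art = pa$p1,
            p_vs0 = pv$p0, p_vs = pv$p1)]
  npy <- nrow(py)
  py[, `:=`(R = rbinom(npy, 1, p_ret),
            A = rbinom(npy, 1, p_art),
            S = rbinom(npy, 1, p_vs),
            has_rna = runif(npy) < cfg$prob_rna)]

  ## ---- visits, consistent with the retention indicator ----
  set.seed(substream_seed(seed, 3L))
  two_visit <- py$R == 1L & !py$is_entry_year
  one_win <- !two_visit & !py$is_entry_year
  yday0 <- year_date(py$year)
  v_person <- v_date <- list()
  ## entry-year: visit on the enrollment date plus one ~6 weeks later
  ent <- py$is_entry_year
  ent_d1 <- pe$enrollment_date[match(py$person_id[ent], pe$person_id)]
  v_person[[1]] <- py$person_id[ent]
  v_date[[1]] <- ent_d1
  v_person[[2]] <- py$person_id[ent]
  v_date[[2]] <- pmin(ent_d1 + sample.int(60, sum(ent), replace = TRUE) + 14L,
                      year_date(py$year[ent], "12-31"))
  ## retained pattern: early + late visit (> 200 days apart)
  n2 <- sum(two_visit)
  v_person[[3]] <- rep(py$person_id[two_visit], 2L)
  v_date[[3]] <- c(yday0[two_visit] + sample.int(76, n2, replace = TRUE) + 3L,
                   yday0[two_visit] + sample.int(80, n2, replace = TRUE) + 280L)
  ## non-retained pattern: 1 + Pois extra visits inside one 86-day window
  n1 <- sum(one_win)
  ws <- sample.int(270, n1, replace = TRUE) + 4L
  v_person[[4]] <- py$person_id[one_win]
  v_date[[4]] <- yday0[one_win] + ws +
    sample.int(86, n1, replace = TRUE) - 1L
  k0 <- rpois(n1, 0.8)
  if (sum(k0) > 0) {
    rep_i <- rep.int(seq_len(n1), k0)
    v_person[[5]] <- py$person_id[one_win][rep_i]
    v_date[[5]] <- yday0[one_win][rep_i] + ws[rep_i] +
      sample.int(86, sum(k0), replace = TRUE) - 1L
  }
  visits <- data.table::data.table(person_id = unlist(v_person),
                                   visit_date = do.call(c, v_date))
  visits <- unique(visits, by = c("person_id", "visit_date"))
  data.table::setorder(visits, person_id, visit_date)

  ## ---- regimens, consistent with the ART indicator ----
  set.seed(substream_seed(seed, 4L))
  art1 <- py$A == 1L
  u <- runif(npy)
  none <- !art1 & u < 0.5
  tnuke <- !art1 & !none & u < 0.75
  dual <- !art1 & !none & !tnuke
  mk_span <- function(sel, agents, nuke) {
    data.table::data.table(
      person_id = py$person_id[sel],
      start_date = year_date(py$year[sel]),
      end_date = year_date(py$year[sel], "12-31"),
      n_agents = agents, is_triple_nuke = nuke)
  }
  regimens <- rbind(mk_span(art1, 3L, FALSE), mk_span(tnuke, 3L, TRUE),
                    mk_span(dual, 2L, FALSE))
  data.table::setorder(regimens, person_id, start_date)

  ## ---- labs: RNA consistent with suppression; CD4 at enrollment ----
  set.seed(substream_seed(seed, 5L))
  rr <- py$has_rna & py$year >= w0
  nr <- sum(rr)
  last_day <- sample.int(160, nr, replace = TRUE) + 199L
  rna_val <- ifelse(py$S[rr] == 1L, runif(nr, 19, 199.4),
                    exp(runif(nr, log(200), log(2e5))))
  labs_rna <- data.table::data.table(
    person_id = py$person_id[rr], lab_date = yday0[rr] + last_day - 1L,
    kind = "rna", value = round(rna_val, 1))
  extra <- runif(nr) < 0.5
  labs_rna2 <- data.table::data.table(
    person_id = py$person_id[rr][extra],
    lab_date = yday0[rr][extra] +
      sample.int(180, sum(extra), replace = TRUE) + 9L,
    kind = "rna", value = round(exp(runif(sum(extra), log(20), log(1e5))), 1))

  set.seed(substream_seed(seed, 6L))
  has_cd4 <- runif(np) < cfg$prob_cd4_lab
  tre <- as.integer(!is.na(pe$expansion_year) &
                      pe$enrollment_year >= pe$expansion_year)
  e_enr <- pe$enrollment_year - pe$expansion_year
  cd4_mu <- cfg$cd4_mean_sqrt +
    re$re_cd4[match(pe$state, re$state)] +
    cfg$cd4_south_effect * (pe$region == "South") +
    cfg$cd4_trend * (pe$enrollment_year - w0)
  cd4_sqrt <- rnorm(np, cd4_mu, cfg$cd4_sd_sqrt)
  cd4_val <- pmax(cd4_sqrt, 1)^2
  cd4_delta <- ifelse(tre == 1L, att_at_event(cfg$att$cd4, pmax(e_enr, 0L)), 0)
  cd4_val <- pmax(round(cd4_val + cd4_delta), 1)
  labs_cd4 <- data.table::data.table(
    person_id = pe$person_id[has_cd4],
    lab_date = pe$enrollment_date[has_cd4] +
      sample.int(150, sum(has_cd4), replace = TRUE) - 1L,
    kind = "cd4", value = cd4_val[has_cd4])
  labs <- rbind(labs_rna, labs_rna2, labs_cd4)
  data.table::setorder(labs, person_id, lab_date, kind)

  ## ---- truth: realized response-scale effects among the treated ----
  tr <- py$treated == 1L & py$year >= w0
  realized <- list(
    retention = realized_att(py[tr & !is_entry_year],
                             "p_ret", "p_ret0"),
    art = realized_att(py[tr], "p_art", "p_art0"),
    vs = realized_att(py[tr & has_rna], "p_vs", "p_vs0"),
    cd4 = list(overall = mean_att_vec(cfg$att$cd4),
               by_event_time = NULL))
  truth <- structure(list(
    config = cfg, seed = seed,
    att = cfg$att, att_scale = cfg$att_scale,
    realized_att = realized,
    state_effects = data.table::setDF(re),
    expansion = stats::setNames(pol$expansion_year, pol$state),
    treated_eta = data.table::setDF(
      py[tr, .(event_time, is_entry_year, has_rna,
               eta_ret = logit(p_ret0), eta_art = logit(p_art0),
               eta_vs = logit(p_vs0))])),
    class = "sim_truth")

  list(persons = data.table::setDF(
         pe[, .(person_id, birth_year, sex, race_eth, state,
                enrollment_date, death_date)]),
       visits = data.table::setDF(visits),
       regimens = data.table::setDF(regimens),
       labs = data.table::setDF(labs),
       policy = pol,
       truth = truth)
}

realized_att <- function(dt, pcol, p0col) {
  d <- dt[[pcol]] - dt[[p0col]]
  list(overall = mean(d),
       by_event_time = tapply(d, dt$event_time, mean))
}

mean_att_vec <- function(v) mean(as.numeric(v))

#' Injected effects on the probability scale
#'
#' Converts the generator's configured treatment effects to marginal
#' probability-scale ATTs by averaging inverse-link differences over the
#' treated person-years' linear predictors -- the estimand the DID module
#' targets for binary outcomes. For `att_scale = "response"` configurations
#' the injected effects are already on the probability scale and are returned
#' (as realized, i.e. after any clipping).
#'
#' @param truth a `sim_truth` object from [simulate_cohort()].
#' @param outcome one of `"retention"`, `"art"`, `"vs"`.
#' @return list with `overall` and `by_event_time` probability-scale ATTs.
#' @export
truth_on_probability_scale <- function(truth, outcome = c("retention", "art",
                                                          "vs")) {
  outcome <- match.arg(outcome)
  truth$realized_att[[outcome]]
}
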