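#' Group-time ATT estimation with not-yet-treated comparisons
#'
#' `did_att()` estimates the average treatment effect on the treated for each
#' (expansion cohort g, calendar year t) cell using a 2-group, pre-vs-post
#' comparison in which the comparison group at period t is the set of states
#' that had *not yet* expanded by t. Estimates are covariate-adjusted by
#' outcome regression: separate regressions of the outcome on covariates are
#' fit among comparison rows in the base period and in period t, and
#' ATT(g,t) is the treated groups' observed base-to-t change minus the change
#' the comparison regressions predict at the treated covariate distribution.
#' With no covariates this reduces exactly to the 2x2 difference-in-means
#' DID. The panel is treated as repeated cross-sections of person-years
#' pooled within group-time cells.
#'
#' Cell estimates are aggregated by length of exposure: theta(e) is the
#' average of ATT(g, g+e) over cohorts observed at event time e, weighted
#' proportionally to the size of each exposure group (person-years in the
#' outcome denominator); the overall effect is the weighted average of the
#' post-expansion theta(e). Inference is by a state-clustered multiplier
#' bootstrap on influence contributions; a Wald test of joint nullity of the
#' pre-period ATTs is the parallel-trends diagnostic.
#'
#' The base period is g-1 for post periods (t >= g); pre-period placebo
#' estimates use the immediately preceding period (`base_period =
#' "varying"`, the default) or g-1 (`"universal"`). Anticipation is assumed
#' absent.
#'
#' @param panel person-year panel from [build_panel()] (or any data.frame
#'   with `state`, `expansion_year`, a time column and an outcome column).
#' @param outcome one of `"retention"`, `"art"`, `"vs"`, or the name of a
#'   numeric column of `panel`.
#' @param covariates `NULL` for the unadjusted estimator, or a character
#'   vector drawn from `c("region", "region_south", "age", "race", "sex")`.
#'   `"age"` enters via a natural cubic spline with 3 knots placed at the
#'   10th/50th/90th percentiles of age among analysis rows (boundary knots at
#'   the observed min/max).
#' @param time_col name of the time column (default `"year"`).
#' @param denom_col optional denominator flag column; defaults to the
#'   outcome's denominator for the three continuum outcomes.
#' @param window analysis window, default `c(2012, 2017)`.
#' @param base_period `"varying"` or `"universal"`.
#' @param reps multiplier-bootstrap replications (default 999).
#' @param seed bootstrap seed.
#' @return object of class `did_att`: `attgt` (per-cell table),
#'   `event_study` (theta(e) with CIs), `overall` (estimate, se, CI),
#'   `pretrend` (Wald statistic, df, p), `weights`, and influence matrices.
#' @export
did_att <- function(panel, outcome = "retention", covariates = NULL,
                    time_col = "year", denom_col = NULL,
                    window = c(2012L, 2017L),
                    base_period = c("varying", "universal"),
                    reps = 999, seed = 1) {
  base_period <- match.arg(base_period)
  default_denoms <- c(retention = "in_retention_denominator",
                      art = "in_art_denominator",
                      vs = "in_vs_denominator")
  ocol <- c(retention = "retained", art = "on_art", vs = "suppressed")[outcome]
  if (is.na(ocol)) ocol <- outcome
  if (is.null(denom_col) && outcome %in% names(default_denoms)) {
    denom_col <- default_denoms[[outcome]]
  }

  dat <- as.data.frame(panel)
  dat <- dat[dat[[time_col]] >= window[1] & dat[[time_col]] <= window[2], ]
  if (!is.null(denom_col)) dat <- dat[dat[[denom_col]] == 1, ]
  dat <- dat[!is.na(dat[[ocol]]), ]
  dat$.y <- as.numeric(dat[[ocol]])
  dat$.t <- as.integer(dat[[time_col]])

  groups <- sort(unique(as.integer(
    dat$expansion_year[!is.na(dat$expansion_year)])))
  groups <- groups[groups > window[1] & groups <= window[2]]
  if (!length(groups)) stop("no treated cohorts inside the analysis window")
  n_treated_states <- length(unique(dat$state[!is.na(dat$expansion_year)]))
  n_comp_states <- length(unique(dat$state[is.na(dat$expansion_year) |
                                             dat$expansion_year > min(groups)]))
  if (n_treated_states < 2 || n_comp_states < 2) {
    stop("fewer than 2 clusters (states) in the treated or comparison group; ",
         "variance is unidentifiable")
  }

  X <- did_design(dat, covariates)

  ## group sizes: person-years in the outcome denominator per cohort
  n_g <- vapply(groups, function(g) {
    sum(dat$expansion_year == g, na.rm = TRUE)
  }, numeric(1))
  names(n_g) <- groups

  states <- sort(unique(dat$state))
  cells <- list()
  for (g in groups) {
    for (tt in seq.int(window[1] + 1L, window[2])) {
      b <- if (tt >= g) g - 1L else
        if (base_period == "varying") tt - 1L else g - 1L
      if (b == tt || b < window[1]) next
      cell <- att_gt_cell(dat, X, g, tt, b, states)
      if (is.null(cell)) next
      cell$g <- as.integer(g); cell$t <- as.integer(tt)
      cell$base <- as.integer(b)
      cell$event_time <- as.integer(tt - g)
      cells[[length(cells) + 1L]] <- cell
    }
  }
  if (!length(cells)) stop("no estimable (g,t) cells")

  attgt <- data.frame(
    g = vapply(cells, `[[`, integer(1), "g"),
    t = vapply(cells, `[[`, integer(1), "t"),
    base = vapply(cells, `[[`, integer(1), "base"),
    event_time = vapply(cells, `[[`, integer(1), "event_time"),
    estimate = vapply(cells, `[[`, numeric(1), "estimate"),
    n_treated = vapply(cells, `[[`, numeric(1), "n_treated"),
    n_comparison = vapply(cells, `[[`, numeric(1), "n_comparison"),
    n_treated_states = vapply(cells, `[[`, numeric(1), "n_treated_states"),
    flagged = vapply(cells, `[[`, logical(1), "flagged"))
  psi_cells <- do.call(cbind, lapply(cells, `[[`, "psi"))  # states x cells
  colnames(psi_cells) <- paste0("g", attgt$g, ".t", attgt$t)

  agg <- aggregate_att(attgt, psi_cells, n_g, window)

  qty_psi <- cbind(psi_cells, agg$psi_theta,
                   overall = agg$psi_overall)
  boot <- multiplier_bootstrap(qty_psi, reps = reps, seed = seed)
  ncell <- nrow(attgt)
  ne <- length(agg$theta)
  attgt$se <- boot$se[seq_len(ncell)]
  attgt$ci_lo <- attgt$estimate - boot$crit[seq_len(ncell)]
  attgt$ci_hi <- attgt$estimate + boot$crit[seq_len(ncell)]

  es <- data.frame(event_time = as.integer(names(agg$theta)),
                   estimate = unname(agg$theta),
                   se = boot$se[ncell + seq_len(ne)],
                   ci_lo = unname(agg$theta) - boot$crit[ncell + seq_len(ne)],
                   ci_hi = unname(agg$theta) + boot$crit[ncell + seq_len(ne)])
  overall <- list(estimate = agg$overall,
                  se = boot$se[ncell + ne + 1L],
                  ci_lo = agg$overall - boot$crit[ncell + ne + 1L],
                  ci_hi = agg$overall + boot$crit[ncell + ne + 1L])

  pre_idx <- which(attgt$event_time < 0)
  pretrend <- if (length(pre_idx)) {
    pretrends_boot(attgt$estimate[pre_idx],
                   boot$draws[, pre_idx, drop = FALSE],
                   attgt$n_treated[pre_idx])
  } else list(statistic = NA_real_, df = 0L, p_value = NA_real_)

  structure(list(outcome = outcome, attgt = attgt, event_study = es,
                 overall = overall, pretrend = pretrend,
                 group_sizes = n_g, weights = agg$weights,
                 psi = qty_psi, reps = reps, seed = seed,
                 covariates = covariates, base_period = base_period),
            class = "did_att")
}

#' Single group-time ATT cell
#'
#' Estimates one ATT(g, t) cell (see [did_att()] for the estimator). Useful
#' for inspecting individual cells and for toy worked examples; no bootstrap
#' is run, so it works on panels with any number of states.
#'
#' @inheritParams did_att
#' @param g expansion cohort (calendar year of expansion).
#' @param t calendar year of the effect.
#' @return list with `estimate`, `g`, `t`, `base`, `n_treated`,
#'   `n_comparison`, `n_treated_states`, `flagged`, and per-state influence
#'   contributions `psi`.
#' @export
group_time_att <- function(panel, g, t, outcome = "retention",
                           covariates = NULL, time_col = "year",
                           denom_col = NULL, window = c(2012L, 2017L),
                           base_period = c("varying", "universal")) {
  base_period <- match.arg(base_period)
  default_denoms <- c(retention = "in_retention_denominator",
                      art = "in_art_denominator",
                      vs = "in_vs_denominator")
  ocol <- c(retention = "retained", art = "on_art", vs = "suppressed")[outcome]
  if (is.na(ocol)) ocol <- outcome
  if (is.null(denom_col) && outcome %in% names(default_denoms)) {
    denom_col <- default_denoms[[outcome]]
  }
  dat <- as.data.frame(panel)
  dat <- dat[dat[[time_col]] >= window[1] & dat[[time_col]] <= window[2], ]
  if (!is.null(denom_col)) dat <- dat[dat[[denom_col]] == 1, ]
  dat <- dat[!is.na(dat[[ocol]]), ]
  dat$.y <- as.numeric(dat[[ocol]])
  dat$.t <- as.integer(dat[[time_col]])
  X <- did_design(dat, covariates)
  b <- if (t >= g) g - 1L else if (base_period == "varying") t - 1L else
    g - 1L
  cell <- att_gt_cell(dat, X, g, t, b, sort(unique(dat$state)))
  if (is.null(cell)) {
    stop(sprintf("cell (g=%d, t=%d) is not estimable (empty treated or comparison group)",
                 g, t))
  }
  cell$g <- as.integer(g); cell$t <- as.integer(t); cell$base <- as.integer(b)
  cell
}

## design matrix for outcome-regression adjustment (NULL -> intercept only)
did_design <- function(dat, covariates) {
  if (is.null(covariates) || !length(covariates)) {
    return(matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)")))
  }
  terms <- "1"
  if ("region" %in% covariates) {
    dat$region <- factor(dat$region,
                         levels = c("Northeast", "South", "Midwest", "West"))
    terms <- c(terms, "region")
  }
  if ("region_south" %in% covariates) terms <- c(terms, "region_south")
  if ("age" %in% covariates) {
    age <- dat$age_at_enrollment
    kn <- unique(stats::quantile(age, c(0.1, 0.5, 0.9), names = FALSE))
    bk <- range(age)
    kn <- kn[kn > bk[1] & kn < bk[2]]
    terms <- c(terms, if (length(kn))
      sprintf("splines::ns(age_at_enrollment, knots = c(%s), Boundary.knots = c(%s))",
              paste(kn, collapse = ","), paste(bk, collapse = ",")) else
        "age_at_enrollment")
  }
  if ("race" %in% covariates) terms <- c(terms, "race_black_nh")
  if ("sex" %in% covariates) {
    dat$sex <- factor(dat$sex, levels = c("male", "female"))
    terms <- c(terms, "sex")
  }
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = dat)
}

## One (g,t) cell: outcome-regression ATT + per-state influence contributions
att_gt_cell <- function(dat, X, g, tt, b, states) {
  is_treat <- !is.na(dat$expansion_year) & dat$expansion_year == g
  ## not-yet-treated by t, excluding cohort g itself (matters for pre-period
  ## placebo cells where t < g)
  is_comp <- (is.na(dat$expansion_year) | dat$expansion_year > tt) & !is_treat
  Tt <- which(is_treat & dat$.t == tt)
  Tb <- which(is_treat & dat$.t == b)
  Ct <- which(is_comp & dat$.t == tt)
  Cb <- which(is_comp & dat$.t == b)
  if (!length(Tt) || !length(Tb)) return(NULL)
  if (!length(Ct) || !length(Cb)) return(NULL)  # all states treated by t
  y <- dat$.y
  Tall <- c(Tb, Tt)
  xbar <- colMeans(X[Tall, , drop = FALSE])

  side_t <- comparison_side(X, y, Ct, dat$state, xbar)
  side_b <- comparison_side(X, y, Cb, dat$state, xbar)
  if (side_t$deficient || side_b$deficient) {
    warning(sprintf(
      "covariate overlap limited in cell (g=%d, t=%d): %d comparison rows at t, %d at base",
      g, tt, length(Ct), length(Cb)), call. = FALSE)
  }
  theta1 <- mean(y[Tt])
  theta2 <- mean(y[Tb])
  dpred <- as.numeric(X[Tall, , drop = FALSE] %*% (side_t$beta - side_b$beta))
  theta3 <- mean(dpred)
  est <- (theta1 - theta2) - theta3

  psi_row <- numeric(nrow(dat))
  psi_row[Tt] <- (y[Tt] - theta1) / length(Tt)
  psi_row[Tb] <- psi_row[Tb] - (y[Tb] - theta2) / length(Tb)
  psi_row[Tall] <- psi_row[Tall] - (dpred - theta3) / length(Tall)
  psi_row[Ct] <- psi_row[Ct] - side_t$contrib
  psi_row[Cb] <- psi_row[Cb] + side_b$contrib

  used <- c(Tall, Ct, Cb)
  psi_state <- rowsum(psi_row[used], dat$state[used])
  psi <- stats::setNames(numeric(length(states)), states)
  psi[rownames(psi_state)] <- psi_state[, 1]
  ## small-sample cluster correction for the treated side: centering within
  ## a side with G clusters shrinks its contribution variance by (G-1)/G;
  ## rescale so the bootstrap variance is approximately unbiased even for
  ## cohorts with very few states. (The comparison side uses
  ## leave-one-cluster-out residuals instead; see comparison_side().)
  tr_states <- unique(dat$state[Tall])
  gt <- length(tr_states)
  if (gt >= 2) psi[tr_states] <- psi[tr_states] * sqrt(gt / (gt - 1))

  list(estimate = est, psi = psi,
       n_treated = as.numeric(length(Tt) + length(Tb)),
       n_comparison = as.numeric(length(Ct) + length(Cb)),
       n_treated_states = as.numeric(length(unique(dat$state[Tt]))),
       flagged = length(unique(dat$state[Tt])) < 2)
}

## OLS with rank-deficiency handling; beta has zeros for dropped columns.
ols_beta <- function(X, y) {
  q <- qr(X)
  keep <- q$pivot[seq_len(q$rank)]
  bk <- qr.coef(qr(X[, keep, drop = FALSE]), y)
  beta <- numeric(ncol(X))
  beta[keep] <- bk
  list(beta = beta, keep = keep, deficient = q$rank < ncol(X))
}

## Comparison-period regression for one cell side: the point estimate uses
## the full-side OLS fit; the per-row influence contributions for the
## coefficient-estimation effect use leave-one-cluster-out residuals
## (CR3-style). With small comparison pools a covariate such as a region
## dummy can be identified by a single state, absorbing that state's entire
## cluster effect -- ordinary residuals then vanish at the cluster level and
## the bootstrap would see none of the coefficient variance; LOO residuals
## restore it.
comparison_side <- function(X, y, idx, state, xbar) {
  Xs <- X[idx, , drop = FALSE]
  ys <- y[idx]
  full <- ols_beta(Xs, ys)
  a <- solve(crossprod(Xs[, full$keep, drop = FALSE]), xbar[full$keep])
  st <- state[idx]
  us <- unique(st)
  e <- numeric(length(idx))
  if (length(us) >= 2) {
    for (s in us) {
      inb <- st == s
      b_s <- ols_beta(Xs[!inb, , drop = FALSE], ys[!inb])
      e[inb] <- ys[inb] - as.numeric(Xs[inb, , drop = FALSE] %*% b_s$beta)
    }
  } else {
    e <- ys - as.numeric(Xs %*% full$beta)
  }
  list(beta = full$beta, deficient = full$deficient,
       contrib = as.numeric(Xs[, full$keep, drop = FALSE] %*% a) * e)
}

## Aggregation: theta(e) with cohort-size weights; overall over post e.
aggregate_att <- function(attgt, psi_cells, n_g, window) {
  evs <- sort(unique(attgt$event_time))
  theta <- numeric(0)
  psi_theta <- NULL
  wlist <- list()
  for (e in evs) {
    idx <- which(attgt$event_time == e)
    w <- n_g[as.character(attgt$g[idx])]
    w <- w / sum(w)
    theta[as.character(e)] <- sum(w * attgt$estimate[idx])
    psi_theta <- cbind(psi_theta,
                       psi_cells[, idx, drop = FALSE] %*% w)
    wlist[[as.character(e)]] <- stats::setNames(w, attgt$g[idx])
  }
  colnames(psi_theta) <- paste0("e", evs)
  post <- evs[evs >= 0]
  v_e <- vapply(post, function(e) {
    gs <- as.integer(names(n_g))
    sum(n_g[gs + e <= window[2]])
  }, numeric(1))
  v_e <- v_e / sum(v_e)
  names(v_e) <- post
  overall <- sum(v_e * theta[as.character(post)])
  psi_overall <- psi_theta[, paste0("e", post), drop = FALSE] %*% v_e
  list(theta = theta, overall = overall,
       psi_theta = psi_theta, psi_overall = as.numeric(psi_overall),
       weights = list(event_time = wlist, post = v_e))
}

#' State-clustered multiplier bootstrap
#'
#' Draws Rademacher multipliers per cluster per replication and perturbs the
#' estimate by the multiplier-weighted sum of cluster influence
#' contributions. Returns the bootstrap SE and the symmetric 95% critical
#' value (the 0.95 quantile of the absolute perturbations), so the CI is
#' `estimate +/- crit`. Deterministic given `seed`.
#'
#' @param psi numeric vector (one influence contribution per cluster) or a
#'   clusters x quantities matrix.
#' @param reps replications (default 999).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return list with `se`, `crit` (per quantity) and the `draws` matrix
#'   (reps x quantities).
#' @export
multiplier_bootstrap <- function(psi, reps = 999, seed = 1,
                                 conf_level = 0.95) {
  if (is.null(dim(psi))) psi <- matrix(psi, ncol = 1)
  nc <- nrow(psi)
  if (nc < 2) stop("fewer than 2 clusters; variance is unidentifiable")
  set.seed(seed)
  mult <- matrix(sample(c(-1, 1), reps * nc, replace = TRUE), reps, nc)
  draws <- mult %*% psi  # reps x quantities
  se <- apply(draws, 2, stats::sd)
  crit <- apply(abs(draws), 2, stats::quantile, probs = conf_level,
                names = FALSE)
  list(se = se, crit = crit, draws = draws)
}

#' Joint Wald test that pre-period ATTs are zero
#'
#' Chi-square test of joint nullity of the pre-expansion (placebo) group-time
#' ATTs, using their bootstrap covariance. Near-singular covariance
#' directions (eigenvalues below `tol` times the largest) are dropped and the
#' degrees of freedom reduced accordingly.
#'
#' @param estimates numeric vector of pre-period ATT estimates.
#' @param V their covariance matrix.
#' @param tol relative eigenvalue tolerance (default 1e-8).
#' @return list with `statistic`, `df`, `p_value`, and `dropped` (number of
#'   collinear components removed).
#' @export
pretrends_wald <- function(estimates, V, tol = 1e-8) {
  V <- as.matrix(V)
  k <- length(estimates)
  eg <- eigen(V, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values, 0)
  df <- sum(pos)
  if (df == 0) return(list(statistic = 0, df = 0L, p_value = 1,
                           dropped = k))
  z <- crossprod(eg$vectors[, pos, drop = FALSE], estimates)
  stat <- sum(z^2 / eg$values[pos])
  list(statistic = as.numeric(stat), df = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       dropped = as.integer(k - df))
}

## Joint test that the pre-period ATTs are zero. The statistic is a
## size-weighted quadratic form sum_j w_j theta_j^2 with fixed weights
## proportional to each cell's treated person-years; its null distribution is
## taken from the multiplier-bootstrap draws (the same form evaluated on each
## draw). Fixed weights avoid inverting a covariance matrix that is poorly
## estimated for cohorts with very few states, while the bootstrap reference
## keeps the test calibrated under the actual cluster structure.
pretrends_boot <- function(estimates, draws, sizes) {
  w <- sizes / sum(sizes)
  qf <- function(x) sum(w * x^2)
  stat <- qf(estimates)
  stat_b <- apply(draws, 1, qf)
  pval <- (1 + sum(stat_b >= stat)) / (length(stat_b) + 1)
  list(statistic = stat, df = as.integer(length(estimates)),
       p_value = pval, weights = w)
}

#' Pre-trends test from a fitted `did_att` object
#'
#' @param fit a [did_att()] fit.
#' @return the fit's pre-trends Wald test (`statistic`, `df`, `p_value`).
#' @export
pretrends_test <- function(fit) {
  stopifnot(inherits(fit, "did_att"))
  fit$pretrend
}

#' @export
print.did_att <- function(x, ...) {
  cat("Staggered DID, outcome:", x$outcome, "\n")
  cat(sprintf("Overall ATT: %.4f (95%% CI %.4f, %.4f), SE %.4f\n",
              x$overall$estimate, x$overall$ci_lo, x$overall$ci_hi,
              x$overall$se))
  cat(sprintf(
    "Pre-trends joint test (%d pre-period cells, bootstrap-calibrated): p = %.3f\n",
    x$pretrend$df, x$pretrend$p_value))
  cat("Event-study estimates:\n")
  print(x$event_study, row.names = FALSE, digits = 4)
  invisible(x)
}

#' DID for CD4 at enrollment (newly enrolled persons, 2013-2014)
#'
#' Applies the group-time ATT machinery to the CD4-at-enrollment outcome
#' among newly enrolled persons, using enrollment year as the time index.
#' Because of data sparsity in initial CD4 counts this analysis uses
#' 2013-2014 only and adjusts for region as South vs other plus the age
#' spline, so it reduces to a single (g = 2014, t = 2014) cell with base
#' period 2013.
#'
#' @param enrollment_cd4 table from [build_panel()].
#' @param covariates default `c("region_south", "age")`.
#' @param years analysis years, default `c(2013, 2014)`.
#' @param reps,seed bootstrap controls.
#' @return a `did_att` object (single cell) on the cells/mm^3 scale.
#' @export
did_cd4 <- function(enrollment_cd4, covariates = c("region_south", "age"),
                    years = c(2013L, 2014L), reps = 999, seed = 1) {
  d <- as.data.frame(enrollment_cd4)
  d <- d[!is.na(d$cd4_at_enrollment) & d$enrollment_year %in%
           seq.int(years[1], years[2]), ]
  d$year <- d$enrollment_year
  did_att(d, outcome = "cd4_at_enrollment", covariates = covariates,
          denom_col = NULL, window = years, reps = reps, seed = seed)
}
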