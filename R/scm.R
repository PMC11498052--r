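#' State-year outcome summaries
#'
#' Collapses the person-year panel to one row per state per year with the
#' proportion retained, on ART, and suppressed (denominators respected) and
#' the number of contributing person-years; optionally adds mean CD4 at
#' enrollment from the enrollment table. State-years with an empty
#' denominator yield a missing cell.
#'
#' @param panel person-year panel from [build_panel()].
#' @param enrollment_cd4 optional enrollment-CD4 table.
#' @return data.frame: `state`, `year`, `prop_retained`, `prop_art`,
#'   `prop_suppressed`, `mean_cd4`, `n_person_years`.
#' @export
summarize_states <- function(panel, enrollment_cd4 = NULL) {
  stopifnot(nrow(panel) > 0)
  p <- data.table::as.data.table(panel)
  s <- p[, .(
    prop_retained = if (sum(in_retention_denominator) > 0)
      mean(retained[in_retention_denominator == 1]) else NA_real_,
    prop_art = if (sum(in_art_denominator) > 0)
      mean(on_art[in_art_denominator == 1]) else NA_real_,
    prop_suppressed = if (sum(in_vs_denominator) > 0)
      mean(suppressed[in_vs_denominator == 1]) else NA_real_,
    n_person_years = .N), by = .(state, year)]
  if (!is.null(enrollment_cd4)) {
    e <- data.table::as.data.table(enrollment_cd4)
    m <- e[!is.na(cd4_at_enrollment),
           .(mean_cd4 = mean(cd4_at_enrollment)),
           by = .(state, year = enrollment_year)]
    s <- merge(s, m, by = c("state", "year"), all.x = TRUE)
  } else s[, mean_cd4 := NA_real_]
  data.table::setorder(s, state, year)
  data.table::setDF(s)
}

#' Synthetic-control donor weights (simplex-constrained least squares)
#'
#' Solves \eqn{\min_w \|y - D w\|^2} subject to \eqn{w \ge 0, \sum w = 1}
#' with an active-set algorithm on the KKT system: the equality-constrained
#' problem is solved on the current support, negative-weight donors are
#' dropped, and excluded donors with negative KKT multipliers re-enter until
#' optimality. Deterministic; exact for these small problems.
#'
#' @param y treated unit's pre-period outcome vector.
#' @param D pre-period outcome matrix, one column per donor.
#' @param tol numerical tolerance.
#' @return named weight vector on the probability simplex (tiny negative
#'   values are clipped to zero and the weights renormalized).
#' @export
scm_weights <- function(y, D, tol = 1e-10) {
  D <- as.matrix(D)
  stopifnot(length(y) == nrow(D))
  if (nrow(D) < 2) stop("need at least 2 pre-periods")
  if (ncol(D) < 2) stop("need at least 2 donors")
  nd <- ncol(D)
  G <- crossprod(D)
  h <- crossprod(D, y)
  solve_support <- function(S) {
    k <- length(S)
    K <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(2 * h[S], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      solve(K + diag(1e-12, k + 1), rhs)
    })
    list(w = sol[seq_len(k)], mu = sol[k + 1])
  }
  S <- seq_len(nd)
  w <- rep(1 / nd, nd)
  mu <- 0
  for (iter in seq_len(200L * nd)) {
    sol <- solve_support(S)
    if (any(sol$w < -tol)) {
      drop <- S[which.min(sol$w)]
      S <- setdiff(S, drop)
      if (!length(S)) stop("active-set failure: empty support")
      next
    }
    w <- numeric(nd)
    w[S] <- pmax(sol$w, 0)
    mu <- sol$mu
    ## KKT: lambda_j = 2 d_j'(Dw - y) + mu must be >= 0 for excluded donors
    lambda <- 2 * (G %*% w - h) + mu
    out <- setdiff(seq_len(nd), S)
    viol <- out[lambda[out] < -sqrt(tol)]
    if (!length(viol)) break
    S <- sort(c(S, out[which.min(lambda[out])]))
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  names(w) <- colnames(D)
  w
}

#' Ridge-augmented synthetic-control counterfactual
#'
#' Classic synthetic control plus an outcome-model bias correction: for each
#' post period t the counterfactual is \eqn{\sum_i w_i y_{it} +
#' (x_{pre} - D_{pre} w)' \hat\beta_t(\lambda)}, where
#' \eqn{\hat\beta_t(\lambda)} is the ridge regression of donor post-period
#' outcomes on donor pre-period outcome vectors. With perfect pre-period fit
#' the correction vanishes; as \eqn{\lambda \to \infty} it also vanishes and
#' the estimator reduces to classic SCM.
#'
#' @param y_pre treated pre-period vector (length p).
#' @param y_post treated post-period vector (length q).
#' @param D_pre p x n donor pre matrix (as in [scm_weights()]).
#' @param D_post q x n donor post matrix.
#' @param w donor weights from [scm_weights()].
#' @param lambda ridge penalty (>= 0).
#' @return list with `counterfactual`, `effect` (observed - counterfactual,
#'   per post period), `imbalance` (pre-period balance gap), `beta`
#'   (p x q ridge coefficients), `pre_rmse`.
#' @export
ridge_augment <- function(y_pre, y_post, D_pre, D_post, w, lambda) {
  D_pre <- as.matrix(D_pre); D_post <- as.matrix(D_post)
  stopifnot(lambda >= 0, length(w) == ncol(D_pre))
  X <- t(D_pre)                      # donors x pre-periods
  imb <- y_pre - as.numeric(D_pre %*% w)
  A <- crossprod(X) + diag(lambda, ncol(X))
  beta <- solve(A, crossprod(X, t(D_post)))   # pre x post
  scm_part <- as.numeric(D_post %*% w)
  correction <- as.numeric(crossprod(beta, imb))
  cf <- scm_part + correction
  list(counterfactual = cf, effect = y_post - cf, imbalance = imb,
       beta = beta, pre_rmse = sqrt(mean(imb^2)))
}

#' Ridge penalty selection by leave-one-pre-period-out cross-validation
#'
#' Each pre period j in turn is held out and treated as a "post" period: the
#' remaining pre periods give the donor weights and the ridge coefficients,
#' and the squared error of the augmented prediction of the treated unit's
#' held-out value is accumulated. The penalty minimizing total CV error over
#' a log-spaced grid is returned (smallest such value on ties; invariant to
#' grid ordering). A degenerate (constant) donor series yields the smallest
#' grid value, flagged.
#'
#' @param y_pre treated pre-period vector (length >= 3).
#' @param D_pre pre x donors matrix.
#' @param grid candidate penalties (default `10^seq(-3, 3, length = 13)`,
#'   scaled by the mean donor variance).
#' @return list with `lambda`, `cv` (per-grid-point error), `grid`,
#'   `degenerate` flag.
#' @export
select_lambda <- function(y_pre, D_pre, grid = NULL) {
  D_pre <- as.matrix(D_pre)
  p <- nrow(D_pre)
  if (p < 3) stop("need at least 3 pre-periods for cross-validation")
  scale <- mean(apply(D_pre, 2, stats::var))
  degenerate <- !is.finite(scale) || scale <= 0
  if (is.null(grid)) {
    grid <- 10^seq(-3, 3, length.out = 13) * max(scale, 1e-8)
  }
  grid <- sort(grid)
  if (degenerate) {
    return(list(lambda = grid[1], cv = rep(NA_real_, length(grid)),
                grid = grid, degenerate = TRUE))
  }
  cv <- numeric(length(grid))
  for (j in seq_len(p)) {
    yj <- y_pre[-j]; Dj <- D_pre[-j, , drop = FALSE]
    wj <- scm_weights(yj, Dj)
    for (k in seq_along(grid)) {
      aug <- ridge_augment(yj, y_pre[j], Dj, D_pre[j, , drop = FALSE],
                           wj, grid[k])
      cv[k] <- cv[k] + (y_pre[j] - aug$counterfactual)^2
    }
  }
  list(lambda = grid[which.min(cv)], cv = cv, grid = grid,
       degenerate = FALSE)
}

#' Augmented SCM for one treated state
#'
#' Fits ridge-augmented synthetic control for a single treated state against
#' donors that remain untreated throughout the state's pre/post horizon
#' (never-expanded states, plus states expanding after the last post year).
#'
#' @param summary state-year summary table from [summarize_states()].
#' @param outcome summary column name (e.g. `"prop_retained"`).
#' @param treated_state 2-letter code.
#' @param policy coarsened policy table.
#' @param window analysis years, default `c(2012, 2017)`.
#' @param lambda ridge penalty; `NULL` (default) selects by
#'   [select_lambda()] when >= 3 pre-periods are available, else 0.
#' @return object of class `scm_fit`: weights, per-year gaps, `pre_rmse`,
#'   `post_effect` (average over post years), `effect_by_year`, `lambda`,
#'   `n_size` (person-years of the treated state).
#' @export
scm_fit_state <- function(summary, outcome, treated_state, policy,
                          window = c(2012L, 2017L), lambda = NULL) {
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  g <- policy$expansion_year[match(treated_state, policy$state)]
  if (is.na(g)) stop(treated_state, " never expanded; nothing to fit")
  yrs <- seq.int(window[1], window[2])
  pre <- yrs[yrs < g]; post <- yrs[yrs >= g]
  if (length(pre) < 2) stop("need >= 2 pre-periods for ", treated_state)
  donors <- policy$state[is.na(policy$expansion_year) |
                           policy$expansion_year > max(post)]
  wide <- make_wide(summary, outcome, yrs)
  donors <- intersect(donors, colnames(wide))
  if (length(donors) < 2) {
    stop("fewer than 2 complete donors for ", treated_state)
  }
  if (!treated_state %in% colnames(wide)) {
    stop("treated state ", treated_state, " has incomplete outcome series")
  }
  y <- wide[, treated_state]
  D <- wide[, donors, drop = FALSE]
  ipre <- match(pre, yrs); ipost <- match(post, yrs)
  w <- scm_weights(y[ipre], D[ipre, , drop = FALSE])
  if (is.null(lambda)) {
    lambda <- if (length(pre) >= 3) {
      select_lambda(y[ipre], D[ipre, , drop = FALSE])$lambda
    } else 0
  }
  aug <- ridge_augment(y[ipre], y[ipost], D[ipre, , drop = FALSE],
                       D[ipost, , drop = FALSE], w, lambda)
  size <- summary$n_person_years[summary$state == treated_state]
  structure(list(state = treated_state, g = g, weights = w,
                 lambda = lambda, pre_years = pre, post_years = post,
                 effect_by_year = stats::setNames(aug$effect, post),
                 post_effect = mean(aug$effect),
                 pre_rmse = aug$pre_rmse, imbalance = aug$imbalance,
                 n_size = sum(size, na.rm = TRUE)),
            class = "scm_fit")
}

make_wide <- function(summary, outcome, yrs) {
  s <- as.data.frame(summary)
  s <- s[s$year %in% yrs, c("state", "year", outcome)]
  states <- sort(unique(s$state))
  wide <- matrix(NA_real_, length(yrs), length(states),
                 dimnames = list(yrs, states))
  wide[cbind(match(s$year, yrs), match(s$state, states))] <- s[[outcome]]
  wide[, colSums(is.na(wide)) == 0, drop = FALSE]
}

#' Average augmented-SCM effect over treated states
#'
#' Size-weighted average of per-state post-expansion effects aligned on
#' event time, with a jackknife-over-treated-states CI.
#'
#' @param fits list of `scm_fit` objects (>= 2).
#' @param conf_level confidence level (default 0.95).
#' @return list with `effect`, `ci_lo`, `ci_hi`, `se`,
#'   `effect_by_event_time`, `pre_rmse_mean`, `n_states`.
#' @export
multistate_effect <- function(fits, conf_level = 0.95) {
  if (length(fits) < 2) {
    stop("need >= 2 treated-state fits to average (got ", length(fits), ")")
  }
  sizes <- vapply(fits, `[[`, numeric(1), "n_size")
  effs <- vapply(fits, `[[`, numeric(1), "post_effect")
  wmean <- function(idx) {
    sum(sizes[idx] * effs[idx]) / sum(sizes[idx])
  }
  n <- length(fits)
  est <- wmean(seq_len(n))
  jk <- vapply(seq_len(n), function(i) wmean(setdiff(seq_len(n), i)),
               numeric(1))
  se <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ## event-time average across states
  ev <- lapply(fits, function(f) {
    data.frame(e = f$post_years - f$g, eff = unname(f$effect_by_year),
               size = f$n_size)
  })
  ev <- do.call(rbind, ev)
  bye <- vapply(split(ev, ev$e), function(d) {
    sum(d$eff * d$size) / sum(d$size)
  }, numeric(1))
  list(effect = est, se = se, ci_lo = est - z * se, ci_hi = est + z * se,
       effect_by_event_time = bye,
       pre_rmse_mean = mean(vapply(fits, `[[`, numeric(1), "pre_rmse")),
       n_states = n)
}

#' Augmented SCM across all treated states for one outcome
#'
#' Fits [scm_fit_state()] for every expansion state with an estimable donor
#' pool and a complete outcome series, then combines with
#' [multistate_effect()]. States that cannot be fit are skipped with a
#' message.
#'
#' @param summary state-year summary from [summarize_states()].
#' @param outcome summary column name.
#' @param policy coarsened policy table.
#' @param window analysis window.
#' @param lambda ridge penalty (`NULL` = CV per state).
#' @return list with `combined` (see [multistate_effect()]), `fits`, and
#'   `skipped` (named reasons).
#' @export
scm_estimate <- function(summary, outcome, policy,
                         window = c(2012L, 2017L), lambda = NULL) {
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  treated <- policy$state[!is.na(policy$expansion_year)]
  fits <- list(); skipped <- character(0)
  for (st in treated) {
    f <- tryCatch(scm_fit_state(summary, outcome, st, policy, window,
                                lambda),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "scm_fit")) fits[[st]] <- f else skipped[st] <- f
  }
  if (length(fits) < 2) {
    stop("fewer than 2 treated states could be fit for ", outcome)
  }
  list(combined = multistate_effect(fits), fits = fits, skipped = skipped)
}
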