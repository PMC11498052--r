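test_that("a donor identical to the treated series gets all the weight", {
  y <- c(0.7, 0.72, 0.74, 0.71)
  # donors with distinct shapes (not parallel to y), so the fit is unique
  D <- cbind(d1 = c(0.60, 0.75, 0.62, 0.80),
             d2 = c(0.90, 0.60, 0.80, 0.55), d3 = y)
  w <- scm_weights(y, D)
  expect_equal(unname(w["d3"]), 1, tolerance = 1e-8)
  expect_equal(sqrt(mean((y - as.numeric(D %*% w))^2)), 0,
               tolerance = 1e-8)
})

test_that("a treated series at the midpoint of two donors gets (0.5, 0.5)", {
  d1 <- c(0.6, 0.65, 0.7); d2 <- c(0.8, 0.85, 0.9)
  y <- (d1 + d2) / 2
  w <- scm_weights(y, cbind(d1, d2))
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("QP objective matches brute-force simplex grid search", {
  set.seed(9)
  for (i in 1:8) {
    nd <- sample(3:6, 1)
    p <- sample(3:5, 1)
    D <- matrix(runif(p * nd), p, nd)
    y <- runif(p)
    w <- scm_weights(y, D)
    obj <- sum((y - D %*% w)^2)
    steps <- if (nd <= 4) 50 else 20
    G <- simplex_grid(nd, steps) / steps
    gobj <- min(colSums((y - D %*% t(G))^2))
    expect_lte(obj, gobj + 1e-4)
    # simplex feasibility
    expect_lt(abs(sum(w) - 1), 1e-8)
    expect_gte(min(w), 0)
  }
})

test_that("perfect pre-period fit makes the ridge augmentation vanish", {
  d1 <- c(0.6, 0.65, 0.7); d2 <- c(0.8, 0.85, 0.9)
  y_pre <- (d1 + d2) / 2
  D_pre <- cbind(d1, d2)
  D_post <- matrix(c(0.72, 0.92), 1, 2)
  w <- scm_weights(y_pre, D_pre)
  aug <- ridge_augment(y_pre, 0.85, D_pre, D_post, w, lambda = 1)
  classic <- as.numeric(D_post %*% w)
  expect_equal(aug$counterfactual, classic, tolerance = 1e-8)
  expect_equal(aug$effect, 0.85 - classic, tolerance = 1e-8)
})

test_that("lambda -> infinity reduces to classic SCM", {
  set.seed(11)
  D_pre <- matrix(runif(12), 4, 3)
  D_post <- matrix(runif(6), 2, 3)
  y_pre <- runif(4); y_post <- runif(2)
  w <- scm_weights(y_pre, D_pre)
  aug <- ridge_augment(y_pre, y_post, D_pre, D_post, w, lambda = 1e12)
  expect_equal(aug$counterfactual, as.numeric(D_post %*% w),
               tolerance = 1e-6)
})

test_that("lambda = 0 with more donors than pre-periods matches the OLS oracle", {
  set.seed(12)
  D_pre <- matrix(runif(18), 3, 6)    # 6 donors, 3 pre-periods
  D_post <- matrix(runif(12), 2, 6)
  y_pre <- runif(3); y_post <- runif(2)
  w <- scm_weights(y_pre, D_pre)
  aug <- ridge_augment(y_pre, y_post, D_pre, D_post, w, lambda = 0)
  # normal-equations oracle: beta_t = (X'X)^-1 X' y_t, X = donors x pre
  X <- t(D_pre)
  for (t in 1:2) {
    beta <- solve(crossprod(X), crossprod(X, D_post[t, ]))
    cf <- sum(D_post[t, ] * w) + sum((y_pre - D_pre %*% w) * beta)
    expect_equal(aug$counterfactual[t], cf, tolerance = 1e-8)
  }
})

test_that("lambda selection: representable data picks the grid minimum,
           noise pushes lambda up, ordering does not matter", {
  d1 <- c(0.6, 0.64, 0.68, 0.72, 0.76)
  d2 <- c(0.8, 0.82, 0.84, 0.86, 0.88)
  y <- 0.4 * d1 + 0.6 * d2           # exactly representable, noiseless
  sel <- select_lambda(y, cbind(d1, d2))
  expect_equal(sel$lambda, min(sel$grid))
  # pure-noise donors: in expectation the CV profile decreases toward
  # large lambda (augmentation only overfits), so the mean profile over
  # instances is lower at the grid maximum and large penalties dominate
  set.seed(14)
  profs <- replicate(40, {
    Dn <- matrix(rnorm(5 * 6), 5, 6)
    select_lambda(rnorm(5), Dn)$cv
  })
  prof <- rowMeans(profs)
  expect_lt(prof[length(prof)], prof[1])
  chosen <- apply(profs, 2, which.min)
  expect_gte(mean(chosen > length(prof) / 2), 0.5)
  # grid-order invariance
  Dn <- matrix(rnorm(5 * 6), 5, 6); yn <- rnorm(5)
  g <- 10^seq(-2, 2, length.out = 9)
  s1 <- select_lambda(yn, Dn, grid = g)
  s2 <- select_lambda(yn, Dn, grid = rev(g))
  expect_equal(s1$lambda, s2$lambda)
  # degenerate constant donors -> smallest grid value, flagged
  Dc <- matrix(0.5, 4, 3)
  sc <- select_lambda(c(0.4, 0.5, 0.6, 0.5), Dc)
  expect_true(sc$degenerate)
  expect_equal(sc$lambda, min(sc$grid))
})

test_that("state-year summaries respect denominators and flag empty cells", {
  p <- data.frame(
    person_id = paste0("p", 1:10), state = "TX", year = 2013L,
    in_retention_denominator = c(rep(1, 10)),
    retained = c(rep(1, 7), rep(0, 3)),
    in_art_denominator = 1, on_art = 1,
    in_vs_denominator = 0, suppressed = NA_integer_)
  s <- summarize_states(p)
  expect_equal(s$prop_retained, 0.7)
  expect_true(is.na(s$prop_suppressed))   # empty denominator -> missing
  expect_equal(s$n_person_years, 10L)
})

test_that("multistate averaging is size-weighted and refuses a single state", {
  mk <- function(st, eff, size) {
    structure(list(state = st, g = 2014L, weights = c(x = 1),
                   lambda = 0, pre_years = 2012:2013, post_years = 2014L,
                   effect_by_year = c("2014" = eff), post_effect = eff,
                   pre_rmse = 0.01, imbalance = 0, n_size = size),
              class = "scm_fit")
  }
  out <- multistate_effect(list(mk("CA", 0.02, 100), mk("NY", 0.04, 100)))
  expect_equal(out$effect, 0.03)
  expect_error(multistate_effect(list(mk("CA", 0.02, 100))), ">= 2")
})

test_that("null generation: averaged SCM effect centers near zero", {
  ss <- small_sim(seed = 23, persons_per_state = 100)
  summ <- summarize_states(ss$panel, ss$enrollment_cd4)
  sc <- scm_estimate(summ, "prop_retained", ss$sim$policy)
  expect_lt(abs(sc$combined$effect), 0.03)
  expect_gte(sc$combined$n_states, 2)
  # simplex feasibility across all fitted states
  for (f in sc$fits) {
    expect_lt(abs(sum(f$weights) - 1), 1e-8)
    expect_gte(min(f$weights), 0)
  }
})
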