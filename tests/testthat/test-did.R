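test_that("a single cell with no covariates equals the closed-form 2x2 DID", {
  p <- toy_panel_2x2()
  cell <- group_time_att(p, g = 2014, t = 2014, outcome = "y",
                         window = c(2013L, 2014L))
  expect_identical(cell$estimate, (0.70 - 0.50) - (0.45 - 0.40))
})

test_that("covariate-balanced adjustment changes little; unbalanced panels differ", {
  ss <- small_sim(seed = 31, persons_per_state = 100)
  un <- did_att(ss$panel, "retention", covariates = NULL, reps = 199,
                seed = 1)
  ad <- did_att(ss$panel, "retention",
                covariates = c("region", "age", "race", "sex"),
                reps = 199, seed = 1)
  expect_lt(abs(un$overall$estimate - ad$overall$estimate), 0.015)
})

test_that("event-time aggregation uses size-proportional weights", {
  # groups of sizes 100 and 300 at e = 0 with ATTs 0.1 and 0.2 -> 0.175
  attgt <- data.frame(g = c(2014L, 2015L), t = c(2014L, 2015L),
                      base = c(2013L, 2014L), event_time = c(0L, 0L),
                      estimate = c(0.1, 0.2))
  psi <- matrix(0, 3, 2)
  agg <- aggregate_att(attgt, psi, c("2014" = 100, "2015" = 300),
                       c(2012L, 2017L))
  expect_equal(unname(agg$theta["0"]), 0.175)
  expect_equal(unname(agg$overall), 0.175)
  expect_equal(sum(agg$weights$post), 1)
})

test_that("a single 2014 cohort's overall effect averages its yearly ATTs", {
  # one treated cohort: every post event time has one cell and group sizes
  # cancel, so overall = mean of ATT(2014, 2014..2017) under equal v_e
  attgt <- data.frame(g = 2014L, t = 2014:2017, base = 2013L,
                      event_time = 0:3,
                      estimate = c(0.10, 0.12, 0.08, 0.06))
  psi <- matrix(0, 4, 4)
  agg <- aggregate_att(attgt, psi, c("2014" = 500), c(2012L, 2017L))
  expect_equal(unname(agg$overall), mean(c(0.10, 0.12, 0.08, 0.06)))
})

test_that("full aggregation equals an independent spreadsheet-style oracle", {
  ss <- small_sim(seed = 31, persons_per_state = 100)
  fit <- did_att(ss$panel, "retention", covariates = NULL, reps = 199,
                 seed = 2)
  a <- fit$attgt
  n_g <- fit$group_sizes
  # independent arithmetic: theta(e), then overall, written out longhand
  for (e in unique(a$event_time)) {
    sub <- a[a$event_time == e, ]
    w <- n_g[as.character(sub$g)] / sum(n_g[as.character(sub$g)])
    expect_equal(unname(fit$event_study$estimate[
      fit$event_study$event_time == e]),
      sum(w * sub$estimate), tolerance = 1e-12)
  }
  post <- sort(unique(a$event_time[a$event_time >= 0]))
  v <- vapply(post, function(e) {
    gs <- as.integer(names(n_g))
    sum(n_g[gs + e <= 2017])
  }, numeric(1))
  v <- v / sum(v)
  th <- fit$event_study$estimate[match(post, fit$event_study$event_time)]
  expect_equal(fit$overall$estimate, sum(v * th), tolerance = 1e-12)
})

test_that("estimates are invariant to row order and state relabeling", {
  ss <- small_sim(seed = 31, persons_per_state = 100)
  p <- ss$panel
  fit1 <- did_att(p, "retention", reps = 99, seed = 3)
  p2 <- p[sample.int(nrow(p)), ]
  fit2 <- did_att(p2, "retention", reps = 99, seed = 3)
  expect_equal(fit1$overall$estimate, fit2$overall$estimate,
               tolerance = 1e-12)
  expect_equal(fit1$attgt$estimate, fit2$attgt$estimate, tolerance = 1e-12)
  # relabel two never-expanded states by swapping their codes
  nv <- unique(p$state[is.na(p$expansion_year)])[1:2]
  p3 <- p
  p3$state[p$state == nv[1]] <- "_tmp_"
  p3$state[p$state == nv[2]] <- nv[1]
  p3$state[p3$state == "_tmp_"] <- nv[2]
  fit3 <- did_att(p3, "retention", reps = 99, seed = 3)
  expect_equal(fit1$overall$estimate, fit3$overall$estimate,
               tolerance = 1e-12)
})

test_that("multiplier bootstrap: zero influence gives a zero-width CI", {
  b <- multiplier_bootstrap(rep(0, 10), reps = 199, seed = 1)
  expect_equal(b$se, 0)
  expect_equal(b$crit, 0)
})

test_that("multiplier bootstrap SE matches sigma/sqrt(n) for an iid mean", {
  set.seed(7)
  n <- 400
  y <- rnorm(n, sd = 2)
  psi <- (y - mean(y)) / n          # influence of the sample mean
  b <- multiplier_bootstrap(psi, reps = 5000, seed = 2)
  analytic <- sd(y) / sqrt(n)
  expect_lt(abs(b$se - analytic) / analytic, 0.05)
})

test_that("multiplier bootstrap refuses a single cluster", {
  expect_error(multiplier_bootstrap(0.3, reps = 99, seed = 1),
               "fewer than 2 clusters")
})

test_that("bootstrap draws are deterministic given the seed", {
  psi <- matrix(rnorm(30), 10, 3)
  b1 <- multiplier_bootstrap(psi, reps = 99, seed = 5)
  b2 <- multiplier_bootstrap(psi, reps = 99, seed = 5)
  expect_identical(b1, b2)
})

test_that("Wald pre-trends utility: single zero estimate with unit variance gives p = 1", {
  out <- pretrends_wald(0, matrix(1, 1, 1))
  expect_equal(out$p_value, 1)
  expect_equal(out$statistic, 0)
  # collinear components are dropped and reported
  V <- matrix(c(1, 1, 1, 1), 2, 2)
  out2 <- pretrends_wald(c(0.1, 0.1), V)
  expect_equal(out2$dropped, 1L)
})

test_that("did_att refuses panels without enough clusters per group", {
  p <- toy_panel_2x2()
  p1 <- p[p$state %in% c("MI", "TX"), ]
  expect_error(did_att(p1, "y", window = c(2013L, 2014L)),
               "fewer than 2 clusters")
})
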