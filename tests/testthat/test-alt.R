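make_cell_data <- function(counts) {
  # counts: list of c(successes, n) keyed by "t.pre","t.post","c.pre","c.post"
  rows <- lapply(names(counts), function(k) {
    grp <- strsplit(k, ".", fixed = TRUE)[[1]]
    n <- counts[[k]][2]; s <- counts[[k]][1]
    data.frame(person_id = paste0(k, "_", seq_len(n)),
               state = if (grp[1] == "t") "CA" else "TX",
               year = if (grp[2] == "pre") 2013L else 2014L,
               y = rep(c(1, 0), c(s, n - s)))
  })
  do.call(rbind, rows)
}

test_that("saturated binomial ITS equals the cross-product ratio of odds", {
  counts <- list("t.pre" = c(30, 100), "t.post" = c(50, 100),
                 "c.pre" = c(40, 100), "c.post" = c(45, 100))
  d <- make_cell_data(counts)
  pol <- mini_policy()
  fit <- fit_its_gee(d, "y", "binomial", pol, covariates = NULL)
  odds <- function(k) counts[[k]][1] / (counts[[k]][2] - counts[[k]][1])
  ror <- (odds("t.post") / odds("t.pre")) / (odds("c.post") / odds("c.pre"))
  expect_equal(fit$estimate, ror, tolerance = 1e-8)
})

test_that("gaussian ITS recovers the closed-form mean-difference DID", {
  cells <- list("t.pre" = 400, "t.post" = 500, "c.pre" = 410,
                "c.post" = 420)
  rows <- lapply(names(cells), function(k) {
    grp <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(person_id = paste0(k, "_", 1:5),
               state = if (grp[1] == "t") "CA" else "TX",
               year = if (grp[2] == "pre") 2013L else 2014L,
               y = cells[[k]] + c(-2, -1, 0, 1, 2))
  })
  d <- do.call(rbind, rows)
  fit <- fit_its_gee(d, "y", "gaussian", mini_policy(), covariates = NULL)
  expect_equal(fit$estimate, (500 - 400) - (420 - 410), tolerance = 1e-10)
  # independence working correlation: point estimate equals OLS exactly
  ols <- lm(y ~ expansion * post,
            data = transform(d, expansion = as.integer(state == "CA"),
                             post = as.integer(year == 2014)))
  expect_equal(fit$beta3, unname(coef(ols)["expansion:post"]),
               tolerance = 1e-10)
})

test_that("with one observation per person the clustered sandwich equals HC0", {
  set.seed(13)
  d <- data.frame(person_id = sprintf("i%03d", 1:200),
                  state = rep(c("CA", "TX"), each = 100),
                  year = rep(c(2013L, 2014L), 100),
                  y = rnorm(200, 100, 10))
  fit <- fit_its_gee(d, "y", "gaussian", mini_policy(), covariates = NULL)
  Vhc <- sandwich::vcovHC(fit$fit, type = "HC0")
  expect_equal(fit$se, sqrt(Vhc["expansion:post", "expansion:post"]),
               tolerance = 1e-10)
})

test_that("saturated propensity model returns empirical cell proportions", {
  # one effective covariate (race); age and sex constant
  d <- data.frame(age_at_enrollment = 40,
                  race_eth = rep(c("black_nh", "white_nh"), each = 100),
                  sex = "male",
                  treated = c(rep(c(1, 0), c(60, 40)),
                              rep(c(1, 0), c(40, 60))))
  ps <- fit_propensity(d)
  expect_equal(unname(ps$score[1]), 0.6, tolerance = 1e-6)
  expect_equal(unname(ps$score[200]), 0.4, tolerance = 1e-6)
  expect_true(all(ps$score > 0 & ps$score < 1))
})

test_that("identical covariate distributions give near-marginal scores", {
  set.seed(5)
  n <- 4000
  d <- data.frame(age_at_enrollment = sample(25:60, n, TRUE),
                  race_eth = sample(c("black_nh", "white_nh"), n, TRUE),
                  sex = sample(c("male", "female"), n, TRUE),
                  treated = rbinom(n, 1, 0.55))
  ps <- fit_propensity(d)
  expect_lt(max(abs(ps$score - mean(d$treated))), 0.12)
})

test_that("ATT weights balance saturated covariate cells exactly", {
  set.seed(6)
  n <- 3000
  race <- sample(c("black_nh", "white_nh"), n, TRUE)
  sex <- sample(c("male", "female"), n, TRUE)
  # race-confounded treatment
  tr <- rbinom(n, 1, ifelse(race == "black_nh", 0.3, 0.7))
  d <- data.frame(age_at_enrollment = 40, race_eth = race, sex = sex,
                  treated = tr, post = rbinom(n, 1, 0.5),
                  person_id = seq_len(n))
  ps <- fit_propensity(d)
  dd <- ps$rows
  w <- ifelse(dd$treated == 1, 1, ps$score / (1 - ps$score))
  for (v in list(as.integer(dd$race_eth == "black_nh"),
                 as.integer(dd$sex == "female"))) {
    m1 <- weighted.mean(v[dd$treated == 1], w[dd$treated == 1])
    m0 <- weighted.mean(v[dd$treated == 0], w[dd$treated == 0])
    expect_equal(m1, m0, tolerance = 1e-6)
  }
})

test_that("PS-weighted DID recovers an injected logit-scale interaction", {
  set.seed(17)
  n <- 50000
  race <- sample(c("black_nh", "white_nh"), n, TRUE)
  sex <- sample(c("male", "female"), n, TRUE)
  age <- sample(25:60, n, TRUE)
  tr <- rbinom(n, 1, 0.5)
  post <- rbinom(n, 1, 0.5)
  eta <- -0.2 + 0.15 * tr + 0.1 * post + 0.3 * tr * post +
    0.2 * (race == "black_nh")
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(age_at_enrollment = age, race_eth = race, sex = sex,
                  treated = tr, post = post, y = y,
                  person_id = seq_len(n))
  ps <- fit_propensity(d)
  fit <- ps_weighted_did(ps$rows, ps$score, "y", "binomial")
  expect_lt(abs(fit$beta3 - 0.3), 0.07)
  expect_true(all(fit$balance < 0.1))
  expect_gt(fit$estimate, 0)
})

test_that("null generation gives an odds ratio near 1 and balanced SMDs", {
  ss <- small_sim(seed = 23, persons_per_state = 100)
  d <- ps_analysis_set(ss$panel, "retention")
  ps <- fit_propensity(d)
  fit <- ps_weighted_did(ps$rows, ps$score, "retained", "binomial")
  expect_lt(abs(log(fit$estimate)), 0.25)
  expect_true(fit$ci_lo < 1 & fit$ci_hi > 1 || abs(log(fit$estimate)) < 0.2)
  expect_true(all(fit$balance < 0.1))
})

test_that("trimming that removes an entire group aborts with a diagnostic", {
  d <- data.frame(treated = rep(c(1, 0), each = 20),
                  post = rep(c(0, 1), 20), y = rbinom(40, 1, 0.5),
                  person_id = 1:40,
                  age_at_enrollment = 40, race_eth = "white_nh",
                  sex = "male")
  scores <- c(rep(0.9, 20), rep(0.1, 20))  # disjoint support
  expect_error(ps_weighted_did(d, scores, "y", "binomial"),
               "entire exposure group")
})
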