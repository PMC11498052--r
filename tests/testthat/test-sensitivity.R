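test_that("generous pre-ACA jurisdictions are removed, others untouched", {
  pol <- default_policy()
  panel <- data.frame(state = c("CA", "TX", "TX", "NY", "WI"),
                      y = 1:5)
  out <- suppressMessages(exclude_generous(panel, pol))
  expect_setequal(out$state, c("TX", "WI"))
  expect_equal(attr(out, "n_removed"), 2L)
  none <- data.frame(state = c("TX", "WI"), y = 1:2)
  out2 <- exclude_generous(none, pol)
  expect_equal(nrow(out2), 2L)
})

test_that("removed person-year count equals the sum over the 7 jurisdictions", {
  ss <- small_sim()
  pol <- default_policy()
  gen <- pol$state[pol$generous_pre_aca]
  out <- suppressMessages(exclude_generous(ss$panel, pol))
  expect_equal(attr(out, "n_removed"),
               sum(table(ss$panel$state)[gen], na.rm = TRUE))
  expect_equal(nrow(out) + attr(out, "n_removed"), nrow(ss$panel))
})

test_that("leave-one-state-out is stable for homogeneous states and shifts
           for a planted outlier", {
  cfg <- sim_config(persons_per_state = 80, n_states = 14,
                    expansion_distribution = c("2014" = 6, "2015" = 1,
                                               "2016" = 1))
  sim <- simulate_cohort(cfg, seed = 19)
  pb <- build_panel(sim$persons, sim$visits, sim$regimens, sim$labs,
                    sim$policy)
  p <- pb$panel
  full <- suppressWarnings(did_att(p, "retention", reps = 199, seed = 4))
  loo <- suppressWarnings(
    leave_one_state_out(p, "retention", reps = 199, seed = 4))
  expect_equal(nrow(loo), length(unique(p$state)))
  expect_equal(loo$excluded_state, sort(unique(p$state)))
  ok <- !loo$flagged
  expect_true(all(loo$estimate[ok] >= full$overall$estimate - 0.08 &
                    loo$estimate[ok] <= full$overall$estimate + 0.08))
  # plant a large idiosyncratic post-period shock in one treated state
  treated_states <- unique(p$state[!is.na(p$expansion_year) &
                                     p$expansion_year == 2014])
  shock_state <- treated_states[1]
  p2 <- p
  hit <- p2$state == shock_state & p2$year >= 2014 &
    p2$in_retention_denominator == 1
  p2$retained[hit] <- 0L
  full2 <- suppressWarnings(did_att(p2, "retention", reps = 199, seed = 4))
  loo2 <- suppressWarnings(
    leave_one_state_out(p2, "retention", states = shock_state, reps = 199,
                        seed = 4))
  shift_out <- abs(loo2$estimate - full2$overall$estimate)
  expect_gt(shift_out, 0.02)  # excluding the shocked state moves the estimate
  expect_gt(full$overall$estimate - 0.02, full2$overall$estimate)
})

test_that("excluding the only treated cohort yields a flagged row", {
  p <- toy_panel_2x2()
  # drop CA so MI is the only treated state; excluding MI leaves none
  p <- p[p$state != "CA", ]
  loo <- leave_one_state_out(p, "y", states = "MI", reps = 99, seed = 1,
                             window = c(2013L, 2014L))
  expect_true(loo$flagged)
})

test_that("volume outcomes count new enrollees and unique patients", {
  panel <- data.frame(
    person_id = c("a", "b", "c", "d", "e", "d", "e"),
    state = "TX",
    year = c(2014L, 2014L, 2014L, 2014L, 2014L, 2013L, 2013L))
  pol <- default_policy()
  tab <- data.frame(
    year = c(2013L, 2014L),
    new = c(2L, 3L),    # d,e first in 2013; a,b,c first in 2014
    total = c(2L, 5L))
  got <- volume_table(panel, pol)
  for (i in 1:2) {
    row <- got[got$year == tab$year[i], ]
    expect_equal(row$new_enrollees, tab$new[i])
    expect_equal(row$total_patients, tab$total[i])
  }
})

test_that("null generation gives volume DID near zero", {
  ss <- small_sim(seed = 23, persons_per_state = 100)
  vo <- volume_outcomes(ss$panel, ss$sim$policy, reps = 199, seed = 5)
  est <- vo$did$new_enrollees$overall$estimate
  # per-state new-enrollee counts are ~12/year at this scale
  expect_lt(abs(est), 4)
})

test_that("run_all produces the requested estimators only and is idempotent", {
  cfg <- sim_config(persons_per_state = 40, n_states = 12,
                    expansion_distribution = c("2014" = 5, "2015" = 1))
  sim <- simulate_cohort(cfg, seed = 29)
  tdir <- withr::local_tempdir()
  res <- suppressWarnings(
    run_all(sim[c("persons", "visits", "regimens", "labs", "policy")],
            outcomes = c("retention", "cd4"), estimators = "did",
            reps = 99, seed = 7, out_dir = tdir))
  expect_null(res$scm)
  expect_true(file.exists(file.path(tdir, "summary.json")))
  expect_true(file.exists(file.path(tdir, "event_study_retention.csv")))
  j1 <- readLines(file.path(tdir, "summary.json"))
  res2 <- suppressWarnings(
    run_all(sim[c("persons", "visits", "regimens", "labs", "policy")],
            outcomes = c("retention", "cd4"), estimators = "did",
            reps = 99, seed = 7, out_dir = tdir))
  j2 <- readLines(file.path(tdir, "summary.json"))
  expect_identical(j1, j2)
})
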