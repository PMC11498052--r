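# Shared fixtures built in code.

# Small 5-state policy table used by the hand-computed fixture.
mini_policy <- function() {
  data.frame(
    state = c("MI", "TX", "CA", "NY", "PA"),
    region = c("Midwest", "South", "West", "Northeast", "Northeast"),
    expansion_date = as.Date(c("2014-04-01", NA, "2014-01-01",
                               "2014-01-01", "2015-01-01")),
    generous_pre_aca = c(FALSE, FALSE, TRUE, TRUE, FALSE))
}

# Five persons exercising the indicator boundary cases:
#  P1/MI: entry-year exclusion; exactly-90-day visit pair (not retained);
#         same-day duplicate RNA on the last date (max value wins);
#         CD4 lab exactly at the 182-day boundary (included).
#  P2/TX: pre-window enrollment (no CD4 row); gap year with no visits;
#         triple-nucleoside regimen excluded from ART; RNA exactly 200
#         (not suppressed, strict <).
#  P3/CA: death censoring; 2-agent regimen not counted as ART; CD4 lab
#         before enrollment excluded.
#  P4/NY: single-visit entry year; regimen overlapping only part of the
#         year still counts; no RNA -> out of suppression denominator.
#  P5/PA: 91-day pair (retained); multi-year regimen span; mid-panel gap
#         years; late expansion (2015) switching treated_in_year mid-panel.
fixture_tables <- function() {
  persons <- data.frame(
    person_id = c("P1", "P2", "P3", "P4", "P5"),
    birth_year = c(1970, 1975, 1980, 1990, 1960),
    sex = c("male", "female", "male", "male", "female"),
    race_eth = c("black_nh", "white_nh", "hispanic", "black_nh",
                 "white_nh"),
    state = c("MI", "TX", "CA", "NY", "PA"),
    enrollment_date = as.Date(c("2013-01-15", "2010-05-10", "2014-02-01",
                                "2016-07-01", "2012-03-05")),
    death_date = as.Date(c(NA, NA, "2015-06-15", NA, NA)))
  visits <- data.frame(
    person_id = c("P1", "P1", "P1", "P1", "P1", "P1",
                  "P2", "P2", "P2", "P2", "P2",
                  "P3", "P3", "P3",
                  "P4",
                  "P5", "P5", "P5", "P5", "P5", "P5"),
    visit_date = as.Date(c(
      "2013-01-15", "2013-04-16", "2014-01-15", "2014-04-15",
      "2015-02-01", "2015-06-01",
      "2010-05-10", "2011-06-01", "2012-03-01", "2012-03-20", "2014-11-05",
      "2014-02-01", "2014-08-01", "2015-03-01",
      "2016-07-01",
      "2012-03-05", "2012-06-20", "2013-01-10", "2013-04-11",
      "2017-05-01", "2017-09-15")))
  regimens <- data.frame(
    person_id = c("P1", "P2", "P3", "P4", "P5"),
    start_date = as.Date(c("2014-03-01", "2014-01-01", "2014-01-01",
                           "2016-06-01", "2013-02-01")),
    end_date = as.Date(c(NA, "2014-12-31", NA, "2016-06-30",
                         "2017-06-30")),
    n_agents = c(3L, 3L, 2L, 3L, 3L),
    is_triple_nuke = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  labs <- data.frame(
    person_id = c("P1", "P1", "P1", "P1", "P1",
                  "P2",
                  "P3", "P3", "P3", "P3",
                  "P4",
                  "P5", "P5"),
    lab_date = as.Date(c(
      "2014-03-01", "2014-09-01", "2015-08-01", "2015-08-01", "2013-07-16",
      "2014-11-05",
      "2015-03-01", "2014-08-01", "2014-02-20", "2014-01-15",
      "2017-01-20",
      "2013-04-11", "2012-09-03")),
    kind = c("rna", "rna", "rna", "rna", "cd4",
             "rna",
             "rna", "rna", "cd4", "cd4",
             "cd4",
             "rna", "cd4"),
    value = c(1000, 150, 150, 250, 400,
              200,
              50, 100000, 350, 999,
              500,
              400, 600))
  list(persons = persons, visits = visits, regimens = regimens,
       labs = labs, policy = mini_policy())
}

# The hand-computed expected person-year panel for fixture_tables().
fixture_expected_panel <- function() {
  df <- read.csv(text = "
person_id,year,state,treated_in_year,in_retention_denominator,retained,in_art_denominator,on_art,in_vs_denominator,suppressed
P1,2013,MI,0,0,NA,1,0,0,NA
P1,2014,MI,1,1,0,1,1,1,1
P1,2015,MI,1,1,1,1,1,1,0
P2,2012,TX,0,1,0,1,0,0,NA
P2,2013,TX,0,1,0,0,NA,0,NA
P2,2014,TX,0,1,0,1,0,1,0
P3,2014,CA,1,0,NA,1,0,1,0
P3,2015,CA,1,1,0,1,0,1,1
P4,2016,NY,1,0,NA,1,1,0,NA
P5,2012,PA,0,0,NA,1,0,0,NA
P5,2013,PA,0,1,1,1,1,1,0
P5,2014,PA,0,1,0,0,NA,0,NA
P5,2015,PA,1,1,0,0,NA,0,NA
P5,2016,PA,1,1,0,0,NA,0,NA
P5,2017,PA,1,1,1,1,1,0,NA
", stringsAsFactors = FALSE)
  df
}

# Expected CD4-at-enrollment rows (newly enrolled in-window persons only).
fixture_expected_cd4 <- function() {
  data.frame(person_id = c("P1", "P3", "P4", "P5"),
             enrollment_year = c(2013, 2014, 2016, 2012),
             cd4_at_enrollment = c(400, 350, NA, 600))
}

# A deterministic multi-state toy panel where the 2x2 cell means are exact.
# Two cohorts of states so did_att() can run end to end: g2014 = {MI, CA},
# never = {TX, NY}. Outcome means by (group, year) are set exactly.
toy_panel_2x2 <- function(n_per_cell = 20) {
  grid <- expand.grid(state = c("MI", "CA", "TX", "NY"),
                      year = c(2013L, 2014L), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    st <- grid$state[i]; yr <- grid$year[i]
    treatg <- st %in% c("MI", "CA")
    m <- if (treatg && yr == 2013) 0.50 else if (treatg) 0.70 else
      if (yr == 2013) 0.40 else 0.45
    k <- round(m * n_per_cell)
    data.frame(person_id = paste0(st, yr, "_", seq_len(n_per_cell)),
               state = st, year = yr,
               expansion_year = if (treatg) 2014L else NA_integer_,
               y = rep(c(1, 0), c(k, n_per_cell - k)))
  }))
  rows
}

# enumerate simplex grid weights (compositions of `steps` into k parts);
# brute-force oracle for the SCM weight QP
simplex_grid <- function(k, steps) {
  if (k == 1) return(matrix(steps, 1, 1))
  out <- list()
  for (i in 0:steps) {
    sub <- simplex_grid(k - 1, steps - i)
    out[[length(out) + 1]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# Small simulated cohort -> derived panel, memoised per test file run.
small_sim <- local({
  cache <- NULL
  function(seed = 11, persons_per_state = 60, ...) {
    key <- paste(seed, persons_per_state, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    sim <- simulate_cohort(sim_config(persons_per_state = persons_per_state,
                                      ...), seed = seed)
    pb <- build_panel(sim$persons, sim$visits, sim$regimens, sim$labs,
                      sim$policy)
    value <- list(sim = sim, panel = pb$panel,
                  enrollment_cd4 = pb$enrollment_cd4)
    cache <<- list(key = key, value = value)
    value
  }
})
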