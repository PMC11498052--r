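#' Build the analysis person-year panel
#'
#' Converts person-level care records into one row per person per contributed
#' calendar year, with the derived care-continuum indicators, their
#' denominator flags, and the state's (coarsened) Medicaid expansion exposure.
#' Also returns one row per newly enrolled person (enrollment year inside the
#' study window) carrying the CD4-at-enrollment measure.
#'
#' Denominators follow the indicator definitions (see
#' [continuum_indicators]): retention is assessed in every contributed year
#' after the year of entry (year of first visit, which may precede the study
#' window); ART receipt in person-years with >= 1 visit; viral suppression in
#' person-years with >= 1 visit and >= 1 RNA result.
#'
#' @param persons data.frame: `person_id`, `birth_year`, `sex`
#'   (`"male"`/`"female"`), `race_eth` (`white_nh`, `black_nh`, `hispanic`,
#'   `other_unknown`), `state`, `enrollment_date`, optional `death_date`.
#' @param visits data.frame: `person_id`, `visit_date`.
#' @param regimens data.frame: `person_id`, `start_date`, `end_date` (`NA` =
#'   ongoing), `n_agents`, `is_triple_nuke`.
#' @param labs data.frame: `person_id`, `lab_date`, `kind` (`"rna"`/`"cd4"`),
#'   `value`.
#' @param policy state policy table (see [default_policy()]).
#' @param window study window years, default `c(2012, 2017)`.
#' @param cd4_window_days CD4-at-enrollment eligibility window (default 182).
#' @return list with elements `panel` (person-year data.frame) and
#'   `enrollment_cd4` (newly-enrolled data.frame).
#' @export
build_panel <- function(persons, visits, regimens, labs, policy,
                        window = c(2012L, 2017L), cd4_window_days = 182) {
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  pe <- data.table::as.data.table(persons)
  vi <- data.table::as.data.table(visits)
  rg <- data.table::as.data.table(regimens)
  lb <- data.table::as.data.table(labs)
  po <- data.table::as.data.table(
    policy[, c("state", "region", "expansion_year")])

  unknown <- setdiff(unique(pe$state), po$state)
  if (length(unknown)) {
    stop("person(s) reference unknown state(s): ",
         paste(unknown, collapse = ", "))
  }

  pe[, enrollment_date := as.Date(enrollment_date)]
  if (!"death_date" %in% names(pe)) pe[, death_date := as.Date(NA)]
  pe[, death_date := as.Date(death_date)]
  vi[, visit_date := data.table::as.IDate(visit_date)]

  ndup <- nrow(vi) - data.table::uniqueN(vi, by = c("person_id", "visit_date"))
  if (ndup > 0) {
    warning("removed ", ndup, " duplicate (person, visit_date) row(s)")
    vi <- unique(vi, by = c("person_id", "visit_date"))
  }
  vi[, year := data.table::year(visit_date)]

  ## follow-up: first..last visit year, clipped to window and death year
  fu <- vi[, .(first_year = min(year), last_year = max(year)), by = person_id]
  fu <- merge(fu, pe[, .(person_id, death_date)], by = "person_id")
  fu[, entry_year := first_year]
  fu[, `:=`(lo = pmax(first_year, window[1]),
            hi = pmin(last_year, window[2]))]
  fu[!is.na(death_date), hi := pmin(hi, date_year(death_date))]
  fu <- fu[lo <= hi]
  n_yr <- fu$hi - fu$lo + 1L
  py <- data.table::data.table(
    person_id = rep(fu$person_id, n_yr),
    entry_year = rep(fu$entry_year, n_yr),
    year = sequence(n_yr, from = fu$lo))

  pe[, enrollment_year := date_year(enrollment_date)]
  pe[, age_at_enrollment := enrollment_year - birth_year]
  pe[, race_black_nh := as.integer(race_eth == "black_nh")]
  py <- merge(py,
              pe[, .(person_id, state, sex, race_eth, race_black_nh,
                     age_at_enrollment, enrollment_year)],
              by = "person_id")
  py <- merge(py, po, by = "state")
  py[, treated_in_year := as.integer(!is.na(expansion_year) &
                                       year >= expansion_year)]

  ## visit-based quantities per person-year
  vi[, vd_int := as.integer(visit_date)]
  vy <- vi[, .(n_visits = .N,
               span_days = max(vd_int) - min(vd_int)),
           by = .(person_id, year)]
  py <- merge(py, vy, by = c("person_id", "year"), all.x = TRUE)
  py[is.na(n_visits), `:=`(n_visits = 0L, span_days = 0)]
  py[, had_visit := n_visits > 0L]

  py[, in_retention_denominator := as.integer(year != entry_year)]
  py[, retained := ifelse(in_retention_denominator == 1L,
                          as.integer(n_visits >= 2L & span_days > 90), NA_integer_)]

  ## ART: any qualifying regimen overlapping the calendar year
  py[, in_art_denominator := as.integer(had_visit)]
  if (nrow(rg)) {
    rg[, `:=`(start_date = as.Date(start_date), end_date = as.Date(end_date))]
    rq <- rg[n_agents >= 3 & !is_triple_nuke]
    if (nrow(rq)) {
      rq[, `:=`(y0 = pmax(date_year(start_date), window[1]),
                y1 = pmin(data.table::fifelse(is.na(end_date), window[2],
                                              date_year(end_date)),
                          window[2]))]
      rq <- rq[y0 <= y1]
      n_sp <- rq$y1 - rq$y0 + 1L
      ry <- data.table::data.table(
        person_id = rep(rq$person_id, n_sp),
        year = sequence(n_sp, from = rq$y0))
      ry <- unique(ry)
      ry[, qualifying := 1L]
      py <- merge(py, ry, by = c("person_id", "year"), all.x = TRUE)
    } else py[, qualifying := NA_integer_]
  } else py[, qualifying := NA_integer_]
  py[, on_art := ifelse(in_art_denominator == 1L,
                        as.integer(!is.na(qualifying)), NA_integer_)]
  py[, qualifying := NULL]

  ## viral suppression: last RNA in the year, same-day ties -> max value
  rna <- lb[kind == "rna"]
  if (nrow(rna)) {
    rna[, lab_date := data.table::as.IDate(lab_date)]
    rna[, year := data.table::year(lab_date)]
    data.table::setorder(rna, person_id, year, lab_date, value)
    last_rna <- rna[, .(last_value = value[.N]), by = .(person_id, year)]
    py <- merge(py, last_rna, by = c("person_id", "year"), all.x = TRUE)
  } else py[, last_value := NA_real_]
  py[, in_vs_denominator := as.integer(had_visit & !is.na(last_value))]
  py[, suppressed := ifelse(in_vs_denominator == 1L,
                            as.integer(last_value < 200), NA_integer_)]
  py[, last_value := NULL]

  ## CD4 at enrollment, newly enrolled persons only
  newly <- pe[enrollment_year >= window[1] & enrollment_year <= window[2] &
                person_id %in% fu$person_id]
  cd4 <- lb[kind == "cd4"]
  cd4[, lab_date := as.Date(lab_date)]
  ecd4 <- merge(newly[, .(person_id, enrollment_year, enrollment_date, state,
                          sex, race_black_nh, age_at_enrollment)],
                cd4[, .(person_id, lab_date, value)],
                by = "person_id", all.x = TRUE)
  ecd4 <- ecd4[is.na(lab_date) |
                 (lab_date >= enrollment_date &
                    lab_date <= enrollment_date + cd4_window_days)]
  data.table::setorder(ecd4, person_id, lab_date, na.last = TRUE)
  ecd4 <- ecd4[, .(cd4_at_enrollment = value[1]),
               by = .(person_id, enrollment_year, state, sex, race_black_nh,
                      age_at_enrollment)]
  ## persons whose only labs fall outside the window drop out of the merge
  ## result above; restore them with NA cd4
  missing_ids <- setdiff(newly$person_id, ecd4$person_id)
  if (length(missing_ids)) {
    add <- newly[person_id %in% missing_ids,
                 .(person_id, enrollment_year, state, sex, race_black_nh,
                   age_at_enrollment)]
    add[, cd4_at_enrollment := NA_real_]
    ecd4 <- rbind(ecd4, add)
  }
  ecd4 <- merge(ecd4, po, by = "state")
  ecd4[, region_south := as.integer(region == "South")]
  ecd4[, treated_at_enrollment := as.integer(!is.na(expansion_year) &
                                               enrollment_year >= expansion_year)]
  data.table::setorder(ecd4, person_id)

  data.table::setorder(py, person_id, year)
  cols <- c("person_id", "year", "state", "region", "expansion_year",
            "treated_in_year", "age_at_enrollment", "sex", "race_eth",
            "race_black_nh", "enrollment_year", "n_visits",
            "in_retention_denominator", "retained",
            "in_art_denominator", "on_art",
            "in_vs_denominator", "suppressed")
  list(panel = data.table::setDF(py[, ..cols]),
       enrollment_cd4 = data.table::setDF(ecd4))
}
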