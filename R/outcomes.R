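#' HIV care continuum indicator definitions
#'
#' These operations implement the annual indicator definitions used throughout
#' the package:
#' * **Retention in care**: at least 2 HIV primary-care visits in a calendar
#'   year separated by strictly more than 90 days; assessed only in calendar
#'   years after the year of entry into care.
#' * **ART receipt**: receipt of a multidrug regimen with >= 3 antiretroviral
#'   agents (excluding triple-nucleoside regimens) at any time in the year,
#'   among person-years with >= 1 clinic visit.
#' * **Viral suppression**: last HIV-1 RNA measurement in the year
#'   < 200 copies/mL, among person-years with >= 1 visit and >= 1 RNA result.
#' * **CD4 at enrollment**: first CD4+ count within 6 months (182 days, both
#'   endpoints included) of the enrollment date.
#'
#' `derive_retention` uses the fact that some pair of dates differs by more
#' than 90 days iff `max(date) - min(date) > 90`, which is O(n) after a scan.
#' When two RNA results share the latest date, the maximum value is used
#' (conservative toward non-suppression).
#'
#' @name continuum_indicators
NULL

#' Calendar years of contributed follow-up
#'
#' A person contributes person-time annually between their first and final
#' clinic visit (or death), clipped to the study window. Years are contiguous:
#' a gap year with no visits between the first and last visit still
#' contributes (with retention 0 when in the denominator).
#'
#' @param visit_dates vector of `Date` visits (any years; not pre-filtered).
#' @param death_date optional `Date`.
#' @param window two-element integer vector, default `c(2012, 2017)`.
#' @return integer vector of contributed calendar years (possibly empty).
#' @export
#' @examples
#' derive_followup(as.Date(c("2013-06-01", "2016-02-01")))
derive_followup <- function(visit_dates, death_date = NULL,
                            window = c(2012L, 2017L)) {
  if (length(visit_dates) == 0) return(integer(0))
  yrs <- as.integer(format(as.Date(visit_dates), "%Y"))
  lo <- max(min(yrs), window[1])
  hi <- min(max(yrs), window[2])
  if (!is.null(death_date) && !is.na(death_date)) {
    hi <- min(hi, as.integer(format(as.Date(death_date), "%Y")))
  }
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

#' Annual retention-in-care indicator
#'
#' @param visits_in_year `Date` vector of visits, all in one calendar year.
#' @param is_entry_year logical; retention is not assessed (returns `NA`) in
#'   the calendar year of entry into care.
#' @param min_gap_days gap rule threshold; a pair of visits must be separated
#'   by strictly more than this many days (default 90).
#' @return 1, 0 or `NA` (not in denominator).
#' @export
derive_retention <- function(visits_in_year, is_entry_year,
                             min_gap_days = 90) {
  if (isTRUE(is_entry_year)) return(NA_integer_)
  if (length(visits_in_year) < 2) return(0L)
  d <- as.numeric(as.Date(visits_in_year))
  as.integer((max(d) - min(d)) > min_gap_days)
}

#' Annual ART receipt indicator
#'
#' @param regimens data.frame with `start_date`, `end_date` (NA = ongoing),
#'   `n_agents`, `is_triple_nuke` for one person.
#' @param year calendar year.
#' @param had_visit logical; the indicator is only defined among person-years
#'   with at least one clinic visit.
#' @return 1, 0 or `NA` (not in denominator).
#' @export
derive_art <- function(regimens, year, had_visit) {
  if (!isTRUE(had_visit)) return(NA_integer_)
  if (is.null(regimens) || nrow(regimens) == 0) return(0L)
  y0 <- as.Date(paste0(year, "-01-01"))
  y1 <- as.Date(paste0(year, "-12-31"))
  s <- as.Date(regimens$start_date)
  e <- as.Date(regimens$end_date)
  overlaps <- s <= y1 & (is.na(e) | e >= y0)
  ok <- regimens$n_agents >= 3 & !regimens$is_triple_nuke & overlaps
  as.integer(any(ok, na.rm = TRUE))
}

#' Annual viral suppression indicator
#'
#' @param rna_labs data.frame with `lab_date` and `value` (copies/mL),
#'   restricted to RNA results in the year.
#' @param had_visit logical.
#' @param threshold suppression threshold in copies/mL (default 200,
#'   strict `<`).
#' @return 1, 0 or `NA` (no visit or no RNA measurement: not in denominator).
#' @export
derive_suppression <- function(rna_labs, had_visit, threshold = 200) {
  if (!isTRUE(had_visit)) return(NA_integer_)
  if (is.null(rna_labs) || nrow(rna_labs) == 0) return(NA_integer_)
  d <- as.Date(rna_labs$lab_date)
  last <- d == max(d)
  v <- max(rna_labs$value[last])  # same-day ties: max value
  as.integer(v < threshold)
}

#' CD4 count at enrollment
#'
#' First available CD4+ count within 6 months of the enrollment date. "6
#' months" is implemented as `window_days` = 182 days, with both endpoints
#' included.
#'
#' @param cd4_labs data.frame with `lab_date` and `value` (cells/mm^3).
#' @param enrollment_date `Date`.
#' @param window_days width of the eligibility window (default 182).
#' @return CD4 value (cells/mm^3) or `NA` if no eligible measurement.
#' @export
derive_cd4_at_enrollment <- function(cd4_labs, enrollment_date,
                                     window_days = 182) {
  if (is.null(cd4_labs) || nrow(cd4_labs) == 0) return(NA_real_)
  d <- as.Date(cd4_labs$lab_date)
  e <- as.Date(enrollment_date)
  keep <- d >= e & d <= e + window_days
  if (!any(keep)) return(NA_real_)
  cd4_labs$value[keep][which.min(d[keep])]
}
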