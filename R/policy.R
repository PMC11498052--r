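#' State Medicaid expansion policy table
#'
#' Returns the bundled policy table for the 50 US states plus the District of
#' Columbia: Census region, ACA Medicaid expansion date (missing for states
#' that had not expanded by the end of 2017), and a flag for the seven
#' jurisdictions with more generous pre-ACA Medicaid income eligibility
#' (>100% of the federal poverty level): AZ, CA, DE, DC, HI, NY, VT.
#'
#' Five states expanded after January 1 of their expansion year (AK, IN, LA,
#' MI, NH); under the January-1 coarsening rule ([coarsen_expansion()]) they
#' are treated as exposed from the start of that calendar year.
#'
#' @param coarsen if `TRUE` (default) the table is passed through
#'   [coarsen_expansion()] so `expansion_year` is populated.
#' @return a `data.frame` with columns `state`, `region`, `expansion_date`,
#'   `generous_pre_aca`, and (when `coarsen = TRUE`) `expansion_year`.
#' @export
#' @examples
#' pol <- default_policy()
#' table(pol$expansion_year, useNA = "ifany")
default_policy <- function(coarsen = TRUE) {
  path <- system.file("extdata", "state_policy.csv", package = "hivdid")
  pol <- utils::read.csv(path, stringsAsFactors = FALSE)
  pol$expansion_date <- as.Date(ifelse(pol$expansion_date == "", NA,
                                       pol$expansion_date))
  if (coarsen) pol <- coarsen_expansion(pol) else pol
}

#' Coarsen expansion dates to calendar years
#'
#' States that expanded Medicaid mid-year are assumed to have expanded at the
#' beginning of that calendar year: exposure is attributed to all residents
#' from January 1 of the expansion year. States with no expansion date remain
#' unexposed throughout.
#'
#' @param policy data.frame with columns `state` and `expansion_date`
#'   (`Date` or ISO-8601 string, `NA` for never-expanded).
#' @return the same table with an integer `expansion_year` column (`NA` for
#'   never-expanded states).
#' @export
#' @examples
#' pol <- data.frame(state = c("MI", "PA", "TX"), region = "x",
#'                   expansion_date = as.Date(c("2014-04-01", "2015-01-01", NA)))
#' coarsen_expansion(pol)$expansion_year
coarsen_expansion <- function(policy) {
  stopifnot(is.data.frame(policy), all(c("state", "expansion_date") %in%
                                         names(policy)))
  unknown <- setdiff(policy$state, all_state_codes())
  if (length(unknown)) {
    stop("unknown state code(s): ", paste(unknown, collapse = ", "))
  }
  ed <- policy$expansion_date
  if (!inherits(ed, "Date")) ed <- as.Date(ed)
  policy$expansion_date <- ed
  policy$expansion_year <- as.integer(format(ed, "%Y"))
  policy
}

#' Count states by expansion year
#'
#' Tabulates expansion cohorts under the January-1 coarsening. By the
#' convention used in published counts, the District of Columbia expanded in
#' 2014 but is not counted as a *state*; set `count_dc = TRUE` to include it.
#'
#' @param policy a coarsened policy table (see [coarsen_expansion()]).
#' @param count_dc logical; include DC in the counts (default `FALSE`).
#' @return named integer vector of state counts by expansion year, with a
#'   `never` element.
#' @export
expansion_counts <- function(policy, count_dc = FALSE) {
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  if (!count_dc) policy <- policy[policy$state != "DC", , drop = FALSE]
  yrs <- policy$expansion_year
  out <- table(factor(yrs, levels = sort(unique(yrs[!is.na(yrs)]))))
  c(setNames(as.integer(out), names(out)), never = sum(is.na(yrs)))
}

#' States with post-January-1 expansion dates
#'
#' @param policy policy table with `expansion_date`.
#' @return character vector of state codes whose expansion date is later than
#'   January 1 of its year (these are coarsened back to January 1).
#' @export
late_expanders <- function(policy) {
  ed <- as.Date(policy$expansion_date)
  ok <- !is.na(ed)
  jan1 <- as.Date(paste0(format(ed[ok], "%Y"), "-01-01"))
  sort(policy$state[ok][ed[ok] > jan1])
}
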