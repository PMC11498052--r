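#' @importFrom stats plogis qlogis rbinom rnorm rpois runif quantile coef
#'   model.matrix lm.fit pchisq sd var glm binomial gaussian predict as.formula
#'   setNames aggregate rnbinom qnorm rgeom
#' @importFrom utils read.csv head
#' @import data.table
NULL

.datatable.aware <- TRUE

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_prob <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)

#' Derive a reproducible substream seed
#'
#' One user-facing seed is streamed into independent substreams (one per
#' generated table / per bootstrap) so that adding a table to the generator
#' does not perturb draws made for earlier tables. Kept below 2^31 - 1.
#'
#' @param seed integer master seed
#' @param k integer substream index
#' @return an integer seed
#' @keywords internal
substream_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483) * 977 + k * 7919) %% 2147483647)
}

## vectorised "date at fixed month-day of each year" without per-element
## string parsing (one as.Date per distinct year)
year_date <- function(years, mmdd = "01-01") {
  u <- sort(unique(years))
  as.Date(paste0(u, "-", mmdd))[match(years, u)]
}

## fast calendar-year extraction
date_year <- function(d) {
  data.table::year(data.table::as.IDate(d))
}

all_state_codes <- function() {
  c("AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "DC", "FL", "GA", "HI",
    "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN",
    "MS", "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH",
    "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA",
    "WV", "WI", "WY")
}

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "person_id", "year", "visit_date", "state", "region",
  "expansion_year", "expansion_date", "treated_in_year", "enrollment_date",
  "death_date", "lab_date", "kind", "value", "start_date", "end_date",
  "n_agents", "is_triple_nuke", "retained", "on_art", "suppressed",
  "in_retention_denominator", "in_art_denominator", "in_vs_denominator",
  "age_at_enrollment", "sex", "race_eth", "race_black_nh", "enrollment_year",
  "region_south", "cd4_at_enrollment", "first_year", "last_year", "entry_year",
  "had_visit", "n_py", "birth_year", "generous_pre_aca", "new_enrollees",
  "total_patients", "qualifying", "is_entry_year", "treated_at_enrollment",
  "idx", "y0", "y1", "lo", "hi", "n_visits", "span_days", "last_value",
  "vd_int",
  "..cols", "event_time", "p_ret", "p_art", "p_vs", "R", "A", "S", "has_rna",
  "state_re", "n_extra", "day1", "day2", "win_start", "treated", "post"
))
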