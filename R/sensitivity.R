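#' Exclude states with generous pre-ACA Medicaid eligibility
#'
#' Removes all person-years from the seven jurisdictions that had Medicaid
#' income eligibility above 100% of the federal poverty level before the
#' ACA (AZ, CA, DE, DC, HI, NY, VT), a sensitivity analysis against
#' exposure measurement error.
#'
#' @param panel person-year panel (or any table with a `state` column).
#' @param policy policy table with the `generous_pre_aca` flag.
#' @return the filtered table, with attribute `n_removed` (rows removed) and
#'   a message logging removal counts per state.
#' @export
exclude_generous <- function(panel, policy) {
  gen <- policy$state[policy$generous_pre_aca]
  drop <- panel$state %in% gen
  if (any(drop)) {
    cnt <- table(panel$state[drop])
    message("excluding generous pre-ACA jurisdictions: ",
            paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  }
  out <- panel[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Leave-one-state-out sensitivity analysis
#'
#' Re-runs the primary staggered DID once per excluded state (same seed each
#' re-run) to assess sensitivity of the overall estimate to state-specific
#' factors. Exclusions that leave no treated or no comparison states are
#' flagged rather than estimated.
#'
#' @param panel person-year panel.
#' @param outcome outcome passed to [did_att()].
#' @param covariates covariates passed to [did_att()].
#' @param states states to exclude one at a time (default: all in panel).
#' @param reps,seed bootstrap controls (the same seed is used for every
#'   re-run).
#' @param ... further arguments to [did_att()].
#' @return data.frame: `excluded_state`, `estimate`, `ci_lo`, `ci_hi`,
#'   `flagged` (TRUE when not estimable), sorted by state.
#' @export
leave_one_state_out <- function(panel, outcome = "retention",
                                covariates = NULL, states = NULL,
                                reps = 999, seed = 1, ...) {
  states <- sort(states %||% unique(panel$state))
  rows <- lapply(states, function(st) {
    sub <- panel[panel$state != st, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(did_att(sub, outcome = outcome,
                               covariates = covariates, reps = reps,
                               seed = seed, ...)),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(excluded_state = st, estimate = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, flagged = TRUE)
    } else {
      data.frame(excluded_state = st, estimate = fit$overall$estimate,
                 ci_lo = fit$overall$ci_lo, ci_hi = fit$overall$ci_hi,
                 flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Patient-volume secondary outcomes
#'
#' State-year counts of newly enrolled patients (persons whose first
#' contributed year is that year) and of total unique patients (all persons
#' contributing that state-year), plus staggered DID estimates treating the
#' counts as state-level outcomes (one row per state-year; cluster = state).
#'
#' @param panel person-year panel.
#' @param policy coarsened policy table.
#' @param reps,seed bootstrap controls.
#' @return list with `table` (state-year counts) and `did` (list with
#'   `new_enrollees` and `total_patients` [did_att()] fits).
#' @export
volume_outcomes <- function(panel, policy, reps = 999, seed = 1) {
  tab <- volume_table(panel, policy)
  did <- list(
    new_enrollees = did_att(tab, outcome = "new_enrollees",
                            covariates = NULL, reps = reps, seed = seed),
    total_patients = did_att(tab, outcome = "total_patients",
                             covariates = NULL, reps = reps, seed = seed))
  list(table = tab, did = did)
}

#' State-year patient-volume counts
#'
#' @param panel person-year panel.
#' @param policy coarsened policy table.
#' @return data.frame: `state`, `year`, `new_enrollees` (persons whose first
#'   contributed year is that year), `total_patients` (distinct persons
#'   contributing that state-year), `expansion_year`.
#' @export
volume_table <- function(panel, policy) {
  p <- data.table::as.data.table(panel)
  first <- p[, .(first_year = min(year)), by = person_id]
  p <- merge(p, first, by = "person_id")
  tab <- p[, .(new_enrollees = sum(year == first_year),
               total_patients = data.table::uniqueN(person_id)),
           by = .(state, year)]
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  tab <- merge(tab, data.table::as.data.table(
    policy[, c("state", "expansion_year")]), by = "state")
  data.table::setorder(tab, state, year)
  data.table::setDF(tab)
}

#' Run the full estimation pipeline
#'
#' Derives the person-year panel from input tables, runs the requested
#' estimators and sensitivity analyses, and (optionally) writes a JSON
#' summary plus CSV tables to an output directory. Deterministic for fixed
#' inputs and seeds; on a stage failure the completed results are preserved
#' in the returned bundle with the error recorded.
#'
#' @param tables list with `persons`, `visits`, `regimens`, `labs`,
#'   `policy` (as from [simulate_cohort()]), or `NULL` to read CSVs from
#'   `input_dir`.
#' @param input_dir directory containing `persons.csv`, `visits.csv`,
#'   `regimens.csv`, `labs.csv`, `policy.csv` (used when `tables` is NULL).
#' @param outcomes outcomes for the primary DID (default all three binary
#'   outcomes plus CD4).
#' @param estimators subset of `c("did", "its", "ps", "scm")`.
#' @param sensitivity subset of `c("exclude_generous", "leave_one_out",
#'   "volume")`; empty by default (they re-run the DID many times).
#' @param reps,seed bootstrap controls.
#' @param out_dir if non-NULL, results are written there (`summary.json`,
#'   `event_study_<outcome>.csv`, `panel.csv` ...).
#' @return results bundle (list), invisibly when writing to disk.
#' @export
run_all <- function(tables = NULL, input_dir = NULL,
                    outcomes = c("retention", "art", "vs", "cd4"),
                    estimators = c("did", "its", "ps", "scm"),
                    sensitivity = character(0),
                    reps = 999, seed = 1, out_dir = NULL) {
  if (is.null(tables)) {
    stopifnot(!is.null(input_dir))
    rd <- function(f) utils::read.csv(file.path(input_dir, f),
                                      stringsAsFactors = FALSE)
    tables <- list(persons = rd("persons.csv"), visits = rd("visits.csv"),
                   regimens = rd("regimens.csv"), labs = rd("labs.csv"),
                   policy = rd("policy.csv"))
  }
  policy <- tables$policy
  if (!"expansion_year" %in% names(policy)) policy <- coarsen_expansion(policy)
  res <- list(seed = seed, reps = reps, estimators = estimators,
              errors = list())
  pb <- build_panel(tables$persons, tables$visits, tables$regimens,
                    tables$labs, policy)
  res$n_person_years <- nrow(pb$panel)
  res$n_enrollees <- nrow(pb$enrollment_cd4)

  binary <- intersect(outcomes, c("retention", "art", "vs"))
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if ("did" %in% estimators) {
    res$did <- lapply(stats::setNames(binary, binary), function(oc) {
      try_stage(paste0("did_", oc),
                did_att(pb$panel, oc,
                        covariates = c("region", "age", "race", "sex"),
                        reps = reps, seed = seed))
    })
    if ("cd4" %in% outcomes) {
      res$did$cd4 <- try_stage("did_cd4",
                               did_cd4(pb$enrollment_cd4, reps = reps,
                                       seed = seed))
    }
  }
  if ("its" %in% estimators) {
    res$its <- lapply(stats::setNames(binary, binary), function(oc) {
      d <- ps_analysis_set(pb$panel, oc)
      try_stage(paste0("its_", oc),
                fit_its_gee(d, ocol_for(oc), "binomial", policy))
    })
    if ("cd4" %in% outcomes) {
      d <- ps_analysis_set(pb$enrollment_cd4, "cd4")
      res$its$cd4 <- try_stage("its_cd4",
                               fit_its_gee(d, "cd4_at_enrollment",
                                           "gaussian", policy,
                                           covariates = c("region_south",
                                                          "age")))
    }
  }
  if ("ps" %in% estimators) {
    res$ps <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
      try_stage(paste0("ps_", oc), {
        src <- if (oc == "cd4") pb$enrollment_cd4 else pb$panel
        d <- ps_analysis_set(src, oc)
        ps <- fit_propensity(d)
        ps_weighted_did(ps$rows, ps$score,
                        if (oc == "cd4") "cd4_at_enrollment" else
                          ocol_for(oc),
                        if (oc == "cd4") "gaussian" else "binomial")
      })
    })
  }
  if ("scm" %in% estimators) {
    summ <- summarize_states(pb$panel, pb$enrollment_cd4)
    scm_col <- c(retention = "prop_retained", art = "prop_art",
                 vs = "prop_suppressed", cd4 = "mean_cd4")
    res$scm <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
      try_stage(paste0("scm_", oc),
                scm_estimate(summ, scm_col[[oc]], policy)$combined)
    })
  }
  if ("exclude_generous" %in% sensitivity) {
    sub <- exclude_generous(pb$panel, policy)
    res$exclude_generous <- lapply(
      stats::setNames(binary, binary), function(oc) {
        try_stage(paste0("generous_", oc),
                  did_att(sub, oc,
                          covariates = c("region", "age", "race", "sex"),
                          reps = reps, seed = seed))
      })
  }
  if ("leave_one_out" %in% sensitivity) {
    res$leave_one_out <- lapply(
      stats::setNames(binary, binary), function(oc) {
        try_stage(paste0("loo_", oc),
                  leave_one_state_out(pb$panel, oc,
                                      covariates = c("region", "age",
                                                     "race", "sex"),
                                      reps = reps, seed = seed))
      })
  }
  if ("volume" %in% sensitivity) {
    res$volume <- try_stage("volume",
                            volume_outcomes(pb$panel, policy, reps = reps,
                                            seed = seed))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summ <- summarize_run(res)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (oc in names(res$did %||% list())) {
      f <- res$did[[oc]]
      if (!is.null(f)) {
        utils::write.csv(f$event_study,
                         file.path(out_dir,
                                   paste0("event_study_", oc, ".csv")),
                         row.names = FALSE)
      }
    }
    if (length(res$errors)) {
      writeLines(unlist(res$errors), file.path(out_dir, "errors.log"))
    }
  }
  if (length(res$errors)) {
    warning("stages failed: ", paste(names(res$errors), collapse = ", "))
  }
  invisible(res)
}

ocol_for <- function(oc) {
  c(retention = "retained", art = "on_art", vs = "suppressed")[[oc]]
}

## flat numeric summary of a results bundle (JSON-friendly)
summarize_run <- function(res) {
  out <- list(seed = res$seed, reps = res$reps,
              n_person_years = res$n_person_years,
              n_enrollees = res$n_enrollees)
  for (oc in names(res$did %||% list())) {
    f <- res$did[[oc]]
    if (is.null(f)) next
    out[[paste0("did_", oc)]] <- list(
      estimate = f$overall$estimate, ci_lo = f$overall$ci_lo,
      ci_hi = f$overall$ci_hi, pretrend_p = f$pretrend$p_value)
  }
  for (oc in names(res$its %||% list())) {
    f <- res$its[[oc]]
    if (is.null(f)) next
    out[[paste0("its_", oc)]] <- f[c("estimate", "ci_lo", "ci_hi")]
  }
  for (oc in names(res$ps %||% list())) {
    f <- res$ps[[oc]]
    if (is.null(f)) next
    out[[paste0("ps_", oc)]] <- f[c("estimate", "ci_lo", "ci_hi",
                                    "n_trimmed")]
  }
  for (oc in names(res$scm %||% list())) {
    f <- res$scm[[oc]]
    if (is.null(f)) next
    out[[paste0("scm_", oc)]] <- f[c("effect", "ci_lo", "ci_hi",
                                     "pre_rmse_mean")]
  }
  out
}
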