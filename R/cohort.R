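#' Cohort selection configuration
#'
#' Rules used to construct the index-date cohorts: selection window for
#' the qualifying first fill, age limits at index, baseline and follow-up
#' window lengths, and the look-back used for recent-co-exposure
#' exclusions.
#'
#' @param selection_window Length-2 `Date` vector.
#' @param age_min,age_max Inclusive age range (completed years) at index.
#' @param baseline_days,followup_days Window lengths in days.
#' @param exclusion_lookback_days Days before index within which recent
#'   short-acting methylphenidate or dual study-drug exposure excludes the
#'   patient.
#' @param require_adhd_dx Require a pre-index ADHD diagnosis record.
#' @param require_activity Require at least one recorded visit in both the
#'   baseline and the follow-up window.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(selection_window = as.Date(c("2006-01-01",
                                                          "2010-12-31")),
                             age_min = 6L, age_max = 17L,
                             baseline_days = 365L, followup_days = 365L,
                             exclusion_lookback_days = 60L,
                             require_adhd_dx = TRUE,
                             require_activity = TRUE) {
  if (baseline_days <= 0L || followup_days <= 0L)
    stop_config("baseline_days/followup_days", "must be positive")
  if (exclusion_lookback_days < 0L)
    stop_config("exclusion_lookback_days", "must be non-negative")
  structure(list(selection_window = as.Date(selection_window),
                 age_min = as.integer(age_min),
                 age_max = as.integer(age_max),
                 baseline_days = as.integer(baseline_days),
                 followup_days = as.integer(followup_days),
                 exclusion_lookback_days = as.integer(exclusion_lookback_days),
                 require_adhd_dx = isTRUE(require_adhd_dx),
                 require_activity = isTRUE(require_activity)),
            class = "selection_config")
}

#' Assign the index date and index drug for one patient
#'
#' The index date is the date of the first qualifying monotherapy fill of
#' either study drug inside the selection window. A fill qualifies as
#' monotherapy when no fill of the other study drug occurs on the same
#' date. Patients with any qualifying atomoxetine candidate are assigned to
#' the ATX cohort at the first such date, even when a methylphenidate
#' candidate comes earlier (preferential ATX assignment); otherwise the
#' first long-acting methylphenidate candidate indexes the patient.
#'
#' @param fills Data frame of one patient's fills (`patient_id`, `date`,
#'   `drug_class`).
#' @param cfg A [selection_config()].
#' @return `NULL` when the patient has no qualifying candidate, else a list
#'   with `patient_id`, `index_date` and `index_drug`.
#' @export
assign_index <- function(fills, cfg = selection_config()) {
  if (length(unique(fills$patient_id)) > 1L)
    stop("fills must belong to a single patient")
  fills$date <- as.Date(fills$date)
  in_win <- fills$date >= cfg$selection_window[1] &
    fills$date <= cfg$selection_window[2]
  candidate <- function(drug, other) {
    cand <- fills$date[in_win & fills$drug_class == drug]
    other_dates <- fills$date[fills$drug_class == other]
    cand <- cand[!cand %in% other_dates]   # monotherapy on the day
    if (length(cand)) min(cand) else NULL
  }
  atx <- candidate("ATX", "LA_MPH")
  if (!is.null(atx))
    return(list(patient_id = fills$patient_id[1], index_date = atx,
                index_drug = "ATX"))
  la <- candidate("LA_MPH", "ATX")
  if (!is.null(la))
    return(list(patient_id = fills$patient_id[1], index_date = la,
                index_drug = "LA_MPH"))
  NULL
}

#' Apply inclusion/exclusion rules to an index assignment
#'
#' Checks, in rule order: age at index within limits; recorded activity
#' (at least one visit) in both the baseline and follow-up windows plus a
#' pre-index ADHD diagnosis; no receipt of both study drugs at index or
#' within the look-back; no short-acting methylphenidate at index or
#' within the look-back; and at least one further index-drug fill during
#' follow-up (the index-date fill itself does not count). Every violated
#' rule is recorded as a reason label; the patient is eligible iff no rule
#' is violated.
#'
#' @param patient One-row data frame from the bundle's patient table.
#' @param fills,visits The patient's fills and visits.
#' @param idx Result of [assign_index()].
#' @param cfg A [selection_config()].
#' @return `idx` extended with `eligible` and `exclusion_reasons`.
#' @export
apply_exclusions <- function(patient, fills, visits, idx,
                             cfg = selection_config()) {
  reasons <- character(0)
  d0 <- as.Date(idx$index_date)
  fills$date <- as.Date(fills$date)

  if (patient$age_at_index < cfg$age_min || patient$age_at_index > cfg$age_max)
    reasons <- c(reasons, "age_outside_range")

  if (cfg$require_activity) {
    vd <- as.Date(visits$date)
    if (!any(vd >= d0 - cfg$baseline_days & vd < d0))
      reasons <- c(reasons, "no_baseline_activity")
    if (!any(vd > d0 & vd <= d0 + cfg$followup_days))
      reasons <- c(reasons, "no_followup_activity")
  }
  if (cfg$require_adhd_dx && !isTRUE(patient$adhd_dx_pre_index))
    reasons <- c(reasons, "no_adhd_diagnosis")

  lb <- fills$date >= d0 - cfg$exclusion_lookback_days & fills$date <= d0
  if (any(lb & fills$drug_class == "ATX") &&
      any(lb & fills$drug_class == "LA_MPH"))
    reasons <- c(reasons, "both_ATX_LA_MPH_within_60d")
  if (any(lb & fills$drug_class == "SA_MPH"))
    reasons <- c(reasons, "SA_MPH_within_60d")

  fu <- fills$date > d0 & fills$date <= d0 + cfg$followup_days
  if (!any(fu & fills$drug_class == idx$index_drug))
    reasons <- c(reasons, "no_followup_index_fill")

  idx$eligible <- length(reasons) == 0L
  idx$exclusion_reasons <- reasons
  idx
}

#' Flag a novel initiator
#'
#' An eligible patient is a novel initiator when no ADHD-indicated fill
#' (atomoxetine or either methylphenidate formulation) occurs in the
#' baseline window `[index - baseline_days, index)`.
#'
#' @inheritParams apply_exclusions
#' @return Logical.
#' @export
flag_novel_initiator <- function(fills, idx, cfg = selection_config()) {
  d0 <- as.Date(idx$index_date)
  dates <- as.Date(fills$date)
  !any(dates >= d0 - cfg$baseline_days & dates < d0 &
         fills$drug_class %in% adhd_classes())
}

#' Build index cohorts for a whole bundle
#'
#' Runs [assign_index()], [apply_exclusions()] and [flag_novel_initiator()]
#' for every patient, returning one row per patient. `novel_initiator` is
#' defined (non-`NA`) only for eligible patients.
#'
#' @param bundle An EMR bundle.
#' @param cfg A [selection_config()].
#' @return Data frame with columns `patient_id`, `index_date`,
#'   `index_drug`, `eligible`, `exclusion_reasons` (`;`-separated) and
#'   `novel_initiator`.
#' @export
build_cohorts <- function(bundle, cfg = selection_config()) {
  if (!nrow(bundle$patients))
    return(data.frame(patient_id = character(),
                      index_date = as.Date(character()),
                      index_drug = character(), eligible = logical(),
                      exclusion_reasons = character(),
                      novel_initiator = logical(), stringsAsFactors = FALSE))
  rx_split <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  vis_split <- split(bundle$visits, bundle$visits$patient_id)
  empty_rx <- bundle$prescriptions[0, ]
  empty_vis <- bundle$visits[0, ]

  rows <- lapply(seq_len(nrow(bundle$patients)), function(i) {
    p <- bundle$patients[i, ]
    fills <- rx_split[[p$patient_id]] %||% empty_rx
    visits <- vis_split[[p$patient_id]] %||% empty_vis
    idx <- if (nrow(fills)) assign_index(fills, cfg) else NULL
    if (is.null(idx))
      return(data.frame(patient_id = p$patient_id,
                        index_date = as.Date(NA), index_drug = NA_character_,
                        eligible = FALSE,
                        exclusion_reasons = "no_index_candidate",
                        novel_initiator = NA, stringsAsFactors = FALSE))
    idx <- apply_exclusions(p, fills, visits, idx, cfg)
    data.frame(patient_id = idx$patient_id, index_date = idx$index_date,
               index_drug = idx$index_drug, eligible = idx$eligible,
               exclusion_reasons = paste(idx$exclusion_reasons,
                                         collapse = ";"),
               novel_initiator = if (idx$eligible)
                 flag_novel_initiator(fills, idx, cfg) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attrition report
#'
#' Counts patients per exclusion reason, in rule order, plus the eligible
#' totals by cohort and novel-initiator status.
#'
#' @param cohorts Output of [build_cohorts()].
#' @return A list suitable for JSON serialization.
#' @export
attrition_report <- function(cohorts) {
  reason_order <- c("no_index_candidate", "age_outside_range",
                    "no_baseline_activity", "no_followup_activity",
                    "no_adhd_diagnosis", "both_ATX_LA_MPH_within_60d",
                    "SA_MPH_within_60d", "no_followup_index_fill")
  all_reasons <- unlist(strsplit(cohorts$exclusion_reasons[
    !cohorts$eligible & nzchar(cohorts$exclusion_reasons)], ";"))
  counts <- vapply(reason_order, function(r) sum(all_reasons == r),
                   integer(1))
  el <- cohorts[cohorts$eligible, , drop = FALSE]
  list(n_patients = nrow(cohorts),
       n_eligible = nrow(el),
       exclusion_counts = as.list(counts),
       eligible_by_cohort = as.list(table(el$index_drug)),
       novel_initiators_by_cohort =
         as.list(table(el$index_drug[el$novel_initiator])))
}
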