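#' Gap rule governing treatment-pattern classification
#'
#' Thresholds and conventions for the refill-gap algorithm that classifies
#' persistence, discontinuation, switching, restarting and augmentation
#' over a fixed follow-up window.
#'
#' Discontinuation is a gap in index-drug coverage of at least
#' `standard_gap_days` (default 30) after the last supplied day, with the
#' discontinuation date set `standard_gap_days` into the gap. Gaps that
#' begin around the May-July school holidays are tolerated up to
#' `holiday_gap_days` (default 90) to accommodate sanctioned summer "drug
#' holidays". A switch is the first fill of a non-index ADHD or
#' mental-health class within `switch_window_days` of the end of coverage
#' carrying at least `switch_min_supply_days` of supply; an augmentation is
#' the first such fill whose own supply overlaps index coverage on at least
#' `augment_min_overlap_days` distinct days.
#'
#' @param standard_gap_days Days of uncovered gap that end an episode.
#' @param holiday_gap_days Tolerated gap length when the gap qualifies as a
#'   summer drug holiday.
#' @param holiday_months Integer months (default May, June, July) in which
#'   long gaps are sanctioned.
#' @param switch_window_days Window after the end of coverage in which a
#'   qualifying fill counts as a switch.
#' @param switch_min_supply_days Minimum supply of the switch fill.
#' @param augment_min_overlap_days Minimum days of concurrent supply for
#'   augmentation.
#' @param followup_days Length of the follow-up window (days from index).
#' @param stockpile If `TRUE` (default) an early refill extends coverage
#'   forward from the end of the previous supply; if `FALSE` overlapping
#'   supply is wasted.
#' @param holiday_applies One of `"first_standard_days"` (default: the long
#'   threshold applies when any of the first `standard_gap_days` uncovered
#'   days falls in a holiday month) or `"gap_start"` (only the first
#'   uncovered day is checked).
#' @param switch_anchor One of `"last_covered_day"` (default) or
#'   `"discontinuation_date"`: the day from which the switch window is
#'   measured.
#' @param persistence_includes_gap If `TRUE` (default) persistence runs up
#'   to the day before the discontinuation date (so the permitted gap days
#'   count); if `FALSE` it stops at the end of supplied coverage.
#' @return An object of class `gap_rule`.
#' @export
gap_rule <- function(standard_gap_days = 30L,
                     holiday_gap_days = 90L,
                     holiday_months = 5:7,
                     switch_window_days = 30L,
                     switch_min_supply_days = 30L,
                     augment_min_overlap_days = 30L,
                     followup_days = 365L,
                     stockpile = TRUE,
                     holiday_applies = c("first_standard_days", "gap_start"),
                     switch_anchor = c("last_covered_day",
                                       "discontinuation_date"),
                     persistence_includes_gap = TRUE) {
  rule <- list(standard_gap_days = as.integer(standard_gap_days),
               holiday_gap_days = as.integer(holiday_gap_days),
               holiday_months = as.integer(holiday_months),
               switch_window_days = as.integer(switch_window_days),
               switch_min_supply_days = as.integer(switch_min_supply_days),
               augment_min_overlap_days = as.integer(augment_min_overlap_days),
               followup_days = as.integer(followup_days),
               stockpile = isTRUE(stockpile),
               holiday_applies = match.arg(holiday_applies),
               switch_anchor = match.arg(switch_anchor),
               persistence_includes_gap = isTRUE(persistence_includes_gap))
  if (rule$holiday_gap_days < rule$standard_gap_days)
    stop_config("holiday_gap_days", "must be >= standard_gap_days")
  if (any(unlist(rule[1:7]) <= 0L))
    stop_config("gap_rule", "all day thresholds must be positive")
  structure(rule, class = "gap_rule")
}

#' Build a supply timeline for the index drug
#'
#' Converts a patient's index-drug fills into ordered, disjoint intervals
#' of supplied days, expressed as 0-based day offsets from the index date
#' and truncated at the end of follow-up (day `followup_days - 1`). With
#' stockpiling (the default), a refill made before the previous supply runs
#' out starts contributing the day after accumulated coverage ends, so
#' early refills extend coverage forward rather than being wasted.
#'
#' @param fills Data frame of the patient's index-drug fills with columns
#'   `date` and `supply_days`; must include a fill on the index date.
#' @param idx List or one-row data frame with `patient_id` and `index_date`.
#' @param rule A [gap_rule()].
#' @return An object of class `supply_timeline` with the interval table
#'   (`start`, `end` day offsets), the index date and the follow-up bounds.
#' @export
build_timeline <- function(fills, idx, rule = gap_rule()) {
  if (!nrow(fills)) stop("no index-drug fills supplied")
  if (any(fills$supply_days <= 0L)) stop("fills must have positive supply")
  day <- as.integer(as.Date(fills$date) - as.Date(idx$index_date))
  o <- order(day)
  day <- day[o]
  supply <- as.integer(fills$supply_days)[o]
  if (day[1] != 0L) stop("first fill must fall on the index date")
  last_day <- rule$followup_days - 1L

  starts <- integer(0); ends <- integer(0)
  cur_s <- NA_integer_; cur_e <- -1L
  for (k in seq_along(day)) {
    if (day[k] > last_day) break
    s <- if (rule$stockpile) max(day[k], cur_e + 1L) else day[k]
    e <- s + supply[k] - 1L
    if (is.na(cur_s)) {
      cur_s <- s; cur_e <- e
    } else if (s <= cur_e + 1L) {
      cur_e <- max(cur_e, e)
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- s; cur_e <- e
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  ends <- pmin(ends, last_day)
  keep <- starts <= last_day
  structure(list(patient_id = idx$patient_id,
                 index_date = as.Date(idx$index_date),
                 intervals = data.frame(start = starts[keep],
                                        end = ends[keep]),
                 followup_days = rule$followup_days),
            class = "supply_timeline")
}

# months of the calendar days at offsets `offs` from `index_date`
offset_months <- function(index_date, offs) {
  as.integer(format(index_date + offs, "%m"))
}

#' Detect discontinuation of index therapy
#'
#' Scans the gaps between supplied intervals (including the terminal gap up
#' to the end of follow-up). A gap triggers discontinuation when its length
#' reaches the applicable threshold: the long holiday threshold when the
#' start of the gap falls in (or, under the default convention, when any of
#' its first `standard_gap_days` days falls in) a holiday month, the
#' standard threshold otherwise. The discontinuation date sits the
#' threshold number of days into the gap; events landing beyond follow-up
#' are discarded.
#'
#' @param tl A [build_timeline()] result.
#' @param rule A [gap_rule()].
#' @return `NULL`, or a list with `disc_day` (day offset of the
#'   discontinuation date), `gap_start`, `gap_length` and `threshold`.
#' @export
detect_discontinuation <- function(tl, rule = gap_rule()) {
  iv <- tl$intervals
  last_day <- rule$followup_days - 1L
  gap_starts <- c(if (nrow(iv) > 1L) iv$end[-nrow(iv)] + 1L,
                  iv$end[nrow(iv)] + 1L)
  gap_ends <- c(if (nrow(iv) > 1L) iv$start[-1L] - 1L, last_day)
  for (g in seq_along(gap_starts)) {
    gs <- gap_starts[g]; ge <- gap_ends[g]
    if (gs > ge || gs > last_day) next
    len <- ge - gs + 1L
    probe <- switch(rule$holiday_applies,
                    first_standard_days = gs:(gs + rule$standard_gap_days - 1L),
                    gap_start = gs)
    thr <- if (any(offset_months(tl$index_date, probe) %in%
                   rule$holiday_months))
      rule$holiday_gap_days else rule$standard_gap_days
    if (len >= thr) {
      disc <- gs + thr
      if (disc <= last_day)
        return(list(disc_day = disc, gap_start = gs, gap_length = len,
                    threshold = thr))
      return(NULL)
    }
  }
  NULL
}

#' Classify a switch after discontinuation
#'
#' Among patients with a discontinuation, the earliest fill of a non-index
#' ADHD- or mental-health-indicated class that falls within the switch
#' window after the end of index coverage (or after the discontinuation
#' date, depending on the configured anchor) and carries the minimum
#' supply becomes the switch; only this first switch is recorded.
#'
#' @param disc Result of [detect_discontinuation()] (must be non-`NULL`).
#' @param non_index_fills Data frame of the patient's non-index fills with
#'   columns `day` (offset from index), `drug_class`, `supply_days`.
#' @param rule A [gap_rule()].
#' @param index_drug The index drug class label.
#' @return `NULL`, or a list with `switch_day` and `switch_to_class`.
#' @export
classify_switch <- function(disc, non_index_fills, rule = gap_rule(),
                            index_drug = "ATX") {
  if (is.null(disc)) return(NULL)
  last_day <- rule$followup_days - 1L
  anchor <- switch(rule$switch_anchor,
                   last_covered_day = disc$gap_start - 1L,
                   discontinuation_date = disc$disc_day)
  f <- non_index_fills
  f$day <- as.integer(f$day)
  f$supply_days <- as.integer(f$supply_days)
  f <- f[f$drug_class %in% change_classes(index_drug) &
           f$day > anchor &
           f$day <= anchor + rule$switch_window_days &
           f$day <= last_day &
           f$supply_days >= rule$switch_min_supply_days, , drop = FALSE]
  if (!nrow(f)) return(NULL)
  f <- f[order(f$day, f$drug_class), , drop = FALSE]
  list(switch_day = f$day[1], switch_to_class = f$drug_class[1])
}

#' Detect restart of the index medication
#'
#' A restart is the first index-drug fill strictly after the switch date
#' (for switchers) or discontinuation date (for other discontinuers), on or
#' before the end of follow-up. Assessed only among patients who
#' discontinued or switched.
#'
#' @param index_fill_days Integer day offsets of the index-drug fills.
#' @param change_day The switch day if switched, else the discontinuation
#'   day.
#' @param followup_days Length of follow-up.
#' @return `NULL`, or a list with `restart_day`.
#' @export
detect_restart <- function(index_fill_days, change_day,
                           followup_days = 365L) {
  index_fill_days <- as.integer(index_fill_days)
  cand <- index_fill_days[index_fill_days > change_day &
                            index_fill_days <= followup_days - 1L]
  if (!length(cand)) return(NULL)
  list(restart_day = min(cand))
}

#' Detect augmentation of index therapy
#'
#' The earliest non-index ADHD- or mental-health-class fill whose own
#' supply interval overlaps supplied index coverage on at least the
#' configured number of distinct days; only this first augmentation is
#' recorded, together with its drug class.
#'
#' @inheritParams classify_switch
#' @param tl A [build_timeline()] result.
#' @return `NULL`, or a list with `augment_day` and `augment_class`.
#' @export
detect_augmentation <- function(tl, non_index_fills, rule = gap_rule(),
                                index_drug = "ATX") {
  last_day <- rule$followup_days - 1L
  f <- non_index_fills
  f$day <- as.integer(f$day)
  f$supply_days <- as.integer(f$supply_days)
  f <- f[f$drug_class %in% change_classes(index_drug) &
           f$day >= 0L & f$day <= last_day, , drop = FALSE]
  if (!nrow(f)) return(NULL)
  f <- f[order(f$day, f$drug_class), , drop = FALSE]
  iv <- tl$intervals
  for (k in seq_len(nrow(f))) {
    s <- f$day[k]; e <- min(s + f$supply_days[k] - 1L, last_day)
    overlap <- sum(pmax(0L, pmin(iv$end, e) - pmax(iv$start, s) + 1L))
    if (overlap >= rule$augment_min_overlap_days)
      return(list(augment_day = f$day[k], augment_class = f$drug_class[k]))
  }
  NULL
}

#' Classify one patient's treatment pattern over follow-up
#'
#' Composes timeline construction, discontinuation, switch, restart and
#' augmentation detection into a single per-patient result. Persistence is
#' the number of days from index up to (not including) the earliest of the
#' discontinuation date, switch date and augmentation date, censored at the
#' end of follow-up; the day of the first switch or augmentation is also
#' reported with its interval stratum (0-90, 91-180, 181-360 days).
#'
#' @param fills Data frame of all of the patient's fills (columns `date`,
#'   `drug_class`, `supply_days`).
#' @param idx List or one-row data frame with `patient_id`, `index_date`
#'   and `index_drug`.
#' @param rule A [gap_rule()].
#' @return A one-row data frame (class `pattern_result`) with persistence
#'   days, event flags, event days and the first-change stratum.
#' @export
evaluate_patient <- function(fills, idx, rule = gap_rule()) {
  fills$day <- as.integer(as.Date(fills$date) - as.Date(idx$index_date))
  index_fills <- fills[fills$drug_class == idx$index_drug, , drop = FALSE]
  non_index <- fills[fills$drug_class != idx$index_drug & fills$day >= 0L, ,
                     drop = FALSE]

  tl <- build_timeline(index_fills[index_fills$day >= 0L, , drop = FALSE],
                       idx, rule)
  disc <- detect_discontinuation(tl, rule)
  sw <- classify_switch(disc, non_index, rule, idx$index_drug)
  aug <- detect_augmentation(tl, non_index, rule, idx$index_drug)
  restart <- NULL
  if (!is.null(disc)) {
    change_day <- if (!is.null(sw)) sw$switch_day else disc$disc_day
    restart <- detect_restart(index_fills$day[index_fills$day >= 0L],
                              change_day, rule$followup_days)
  }

  disc_term <- if (is.null(disc)) NA_integer_
               else if (rule$persistence_includes_gap) disc$disc_day
               else disc$gap_start
  ev <- c(disc = disc_term,
          switch = if (is.null(sw)) NA_integer_ else sw$switch_day,
          augment = if (is.null(aug)) NA_integer_ else aug$augment_day)
  persistence <- min(c(ev, rule$followup_days), na.rm = TRUE)
  persistence <- min(persistence, rule$followup_days)

  first_change <- suppressWarnings(min(ev["switch"], ev["augment"],
                                       na.rm = TRUE))
  if (!is.finite(first_change)) first_change <- NA_integer_
  stratum <- if (is.na(first_change)) NA_character_
             else if (first_change <= 90L) "0-90"
             else if (first_change <= 180L) "91-180"
             else if (first_change <= 360L) "181-360"
             else "361+"

  structure(data.frame(
    patient_id = idx$patient_id,
    index_drug = idx$index_drug,
    persistence_days = as.integer(persistence),
    discontinued = !is.null(disc),
    discontinuation_day = if (is.null(disc)) NA_integer_ else disc$disc_day,
    switched = !is.null(sw),
    switch_day = if (is.null(sw)) NA_integer_ else sw$switch_day,
    switch_to_class = if (is.null(sw)) NA_character_ else sw$switch_to_class,
    restarted = !is.null(restart),
    restart_day = if (is.null(restart)) NA_integer_ else restart$restart_day,
    augmented = !is.null(aug),
    augment_day = if (is.null(aug)) NA_integer_ else aug$augment_day,
    augment_class = if (is.null(aug)) NA_character_ else aug$augment_class,
    first_change_day = as.integer(first_change),
    first_change_stratum = stratum,
    stringsAsFactors = FALSE), class = c("pattern_result", "data.frame"))
}

#' Classify treatment patterns for a whole cohort table
#'
#' @param bundle An EMR bundle.
#' @param cohorts Cohort table from [build_cohorts()]; only eligible rows
#'   are evaluated.
#' @param rule A [gap_rule()].
#' @return Data frame of per-patient [evaluate_patient()] rows.
#' @export
evaluate_cohort <- function(bundle, cohorts, rule = gap_rule()) {
  el <- cohorts[cohorts$eligible, , drop = FALSE]
  if (!nrow(el)) return(evaluate_empty())
  rx_split <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  out <- lapply(seq_len(nrow(el)), function(i) {
    idx <- el[i, ]
    evaluate_patient(rx_split[[idx$patient_id]], idx, rule)
  })
  res <- do.call(rbind, out)
  res$novel_initiator <- el$novel_initiator
  rownames(res) <- NULL
  res
}

evaluate_empty <- function() {
  data.frame(patient_id = character(), index_drug = character(),
             persistence_days = integer(), discontinued = logical(),
             discontinuation_day = integer(), switched = logical(),
             switch_day = integer(), switch_to_class = character(),
             restarted = logical(), restart_day = integer(),
             augmented = logical(), augment_day = integer(),
             augment_class = character(), first_change_day = integer(),
             first_change_stratum = character(),
             novel_initiator = logical(), stringsAsFactors = FALSE)
}

pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_

#' Summarize treatment patterns by cohort
#'
#' Produces the per-cohort summary of pattern outcomes: switchers (of the
#' cohort), restarters (of discontinuers-or-switchers), augmenters overall
#' and by augmenting class (of the cohort), the time-to-first-change
#' strata (of patients with a first switch or augmentation), and
#' persistence mean/SD. Percentages over an empty denominator are reported
#' as `NA`, never as 0.
#'
#' @param results Per-patient results from [evaluate_cohort()] (column
#'   `index_drug` labels the cohort).
#' @return A list with components `cohorts` (per-cohort counts and
#'   percentages), `augment_by_class` and `strata` data frames.
#' @export
summarize_patterns <- function(results) {
  if (!nrow(results)) {
    empty_cohorts <- data.frame(cohort = character(), n = integer(),
                                n_switch = integer(), pct_switch = numeric(),
                                n_disc_or_switch = integer(),
                                n_restart = integer(),
                                pct_restart = numeric(),
                                n_augment = integer(),
                                pct_augment = numeric(),
                                mean_persistence = numeric(),
                                sd_persistence = numeric(),
                                stringsAsFactors = FALSE)
    return(list(cohorts = empty_cohorts,
                augment_by_class = data.frame(cohort = character(),
                                              augment_class = character(),
                                              n = integer(),
                                              pct = numeric(),
                                              stringsAsFactors = FALSE),
                strata = data.frame(cohort = character(),
                                    stratum = character(), n = integer(),
                                    pct = numeric(),
                                    stringsAsFactors = FALSE)))
  }
  groups <- split(results, results$index_drug)
  row_for <- function(g, label) {
    n <- nrow(g)
    n_disc_or_switch <- sum(g$discontinued | g$switched)
    n_restart <- sum(g$restarted)
    data.frame(cohort = label, n = n,
               n_switch = sum(g$switched),
               pct_switch = pct(sum(g$switched), n),
               n_disc_or_switch = n_disc_or_switch,
               n_restart = n_restart,
               pct_restart = pct(n_restart, n_disc_or_switch),
               n_augment = sum(g$augmented),
               pct_augment = pct(sum(g$augmented), n),
               mean_persistence = if (n) mean(g$persistence_days) else NA_real_,
               sd_persistence = if (n > 1) stats::sd(g$persistence_days)
                                else NA_real_,
               stringsAsFactors = FALSE)
  }
  cohorts <- do.call(rbind, Map(row_for, groups, names(groups)))

  aug <- do.call(rbind, lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    cls <- change_classes(lab)
    data.frame(cohort = lab, augment_class = cls,
               n = vapply(cls, function(cl)
                 sum(g$augmented & g$augment_class == cl, na.rm = TRUE),
                 integer(1)),
               pct = vapply(cls, function(cl)
                 pct(sum(g$augmented & g$augment_class == cl, na.rm = TRUE),
                     nrow(g)), numeric(1)),
               stringsAsFactors = FALSE)
  }))

  strata_levels <- c("0-90", "91-180", "181-360")
  strata <- do.call(rbind, lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    chg <- g$first_change_stratum[!is.na(g$first_change_stratum) &
                                    g$first_change_stratum %in% strata_levels]
    data.frame(cohort = lab, stratum = strata_levels,
               n = as.integer(table(factor(chg, levels = strata_levels))),
               pct = vapply(strata_levels, function(s)
                 pct(sum(chg == s), length(chg)), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(cohorts) <- rownames(aug) <- rownames(strata) <- NULL
  list(cohorts = cohorts, augment_by_class = aug, strata = strata)
}
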