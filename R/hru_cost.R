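#' Unit-cost configuration
#'
#' Tariff table used to attribute euro costs to counted resource use:
#' per-prescription drug costs by class, outpatient fee-schedule points by
#' specialty converted at a uniform orientation value (default 0.035 euro
#' per point), a weighted-average inpatient admission cost, and a
#' consumer-price index series used to express every component in
#' reference-year euros. The shipped defaults are illustrative
#' placeholders, not reproductions of any licensed tariff catalogue
#' (drug-price list, outpatient fee scale or diagnosis-related-group
#' catalogue); analyses should state the tariff configuration used.
#'
#' @param drug_unit_costs Named euros per prescription by drug class.
#' @param visit_points Named fee-schedule points per visit by specialty.
#' @param orientation_value Euros per point.
#' @param admission_unit_cost Euros per inpatient admission.
#' @param hicp_index Named numeric index series by year.
#' @param reference_year Year whose euros all costs are expressed in.
#' @param source_years Named list: the tariff year of each component
#'   (`drugs`, `visits`, `admissions`), used as the inflation source year.
#' @return An object of class `cost_table`.
#' @export
cost_table <- function(drug_unit_costs = c(ATX = 120, LA_MPH = 45,
                                           SA_MPH = 15, antipsychotic = 40,
                                           tranquilizer = 20,
                                           antidepressant_mood = 25,
                                           anticonvulsant = 30,
                                           hypnotic_sedative = 15,
                                           clonidine = 10, other = 20),
                       visit_points = c(general_internal = 300,
                                        paediatrics = 340,
                                        psychiatry = 500, neurology = 450),
                       orientation_value = 0.035,
                       admission_unit_cost = 3000,
                       hicp_index = c(`2005` = 88.8, `2006` = 90.4,
                                      `2007` = 92.5, `2008` = 95.1,
                                      `2009` = 95.3, `2010` = 96.4,
                                      `2011` = 98.6, `2012` = 100.0),
                       reference_year = 2012L,
                       source_years = list(drugs = 2011L, visits = 2011L,
                                           admissions = 2012L)) {
  tbl <- list(drug_unit_costs = drug_unit_costs,
              visit_points = visit_points,
              orientation_value = orientation_value,
              admission_unit_cost = admission_unit_cost,
              hicp_index = hicp_index,
              reference_year = as.integer(reference_year),
              source_years = lapply(source_years, as.integer))
  if (any(tbl$drug_unit_costs < 0) || any(tbl$visit_points < 0) ||
      tbl$admission_unit_cost < 0)
    stop_config("cost_table", "costs must be non-negative")
  if (tbl$orientation_value <= 0)
    stop_config("orientation_value", "must be positive")
  yrs <- c(tbl$reference_year, unlist(tbl$source_years))
  if (!all(as.character(yrs) %in% names(tbl$hicp_index)))
    stop_config("hicp_index", "must cover the reference and source years")
  structure(tbl, class = "cost_table")
}

#' Read / write a cost table as YAML
#' @param tbl A [cost_table()]. @param path File path.
#' @return `path` invisibly (`write_cost_table`); a `cost_table`
#'   (`read_cost_table`).
#' @export
write_cost_table <- function(tbl, path) {
  yaml::write_yaml(lapply(unclass(tbl), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' @rdname write_cost_table
#' @export
read_cost_table <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("drug_unit_costs", "visit_points", "hicp_index"))
    raw[[f]] <- unlist(raw[[f]])
  do.call(cost_table, raw)
}

#' Count per-patient healthcare resource use over follow-up
#'
#' Tallies, for each eligible patient, events dated in the follow-up
#' window `(index, index + followup_days]`: prescriptions (total, by drug
#' class, and grouped into index drug / other ADHD-indicated / other
#' mental-health / other), outpatient visits by specialty, inpatient
#' admissions and sick notes.
#'
#' @param bundle An EMR bundle.
#' @param cohorts Output of [build_cohorts()]; eligible rows are counted.
#' @param followup_days Follow-up length in days.
#' @return Data frame, one row per eligible patient, with count columns
#'   (`n_rx_<class>`, `n_visits_<specialty>`, grouped totals,
#'   `n_admissions`, `n_sick_notes`).
#' @export
count_hru <- function(bundle, cohorts, followup_days = 365L) {
  el <- cohorts[cohorts$eligible, , drop = FALSE]
  classes <- drug_classes()
  specs <- specialties()
  base_cols <- c("n_rx_total", paste0("n_rx_", classes), "n_rx_index",
                 "n_rx_other_adhd", "n_rx_other_mh",
                 paste0("n_visits_", specs), "n_visits_total",
                 "n_admissions", "n_sick_notes")
  if (!nrow(el)) {
    out <- as.data.frame(matrix(integer(), 0, length(base_cols) + 2L))
    names(out) <- c("patient_id", "index_drug", base_cols)
    return(out)
  }
  rx_s <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  vi_s <- split(bundle$visits, bundle$visits$patient_id)
  ad_s <- split(bundle$admissions, bundle$admissions$patient_id)

  rows <- lapply(seq_len(nrow(el)), function(i) {
    id <- el$patient_id[i]
    d0 <- as.Date(el$index_date[i])
    in_fu <- function(tab, proto) {
      if (is.null(tab)) tab <- proto[0, , drop = FALSE]
      if (!nrow(tab)) return(tab)
      d <- as.Date(tab$date)
      tab[d > d0 & d <= d0 + followup_days, , drop = FALSE]
    }
    rx <- in_fu(rx_s[[id]], bundle$prescriptions)
    vi <- in_fu(vi_s[[id]], bundle$visits)
    ad <- in_fu(ad_s[[id]], bundle$admissions)
    rx_by <- vapply(classes, function(cl) sum(rx$drug_class == cl),
                    integer(1))
    idx_drug <- el$index_drug[i]
    vis_by <- vapply(specs, function(sp) sum(vi$specialty == sp), integer(1))
    row <- c(n_rx_total = sum(rx_by),
             stats::setNames(rx_by, paste0("n_rx_", classes)),
             n_rx_index = rx_by[[idx_drug]],
             n_rx_other_adhd = sum(rx_by[setdiff(adhd_classes(), idx_drug)]),
             n_rx_other_mh = sum(rx_by[mental_health_classes()]),
             stats::setNames(vis_by, paste0("n_visits_", specs)),
             n_visits_total = sum(vis_by),
             n_admissions = nrow(ad),
             n_sick_notes = sum(vi$sick_note))
    c(list(patient_id = id, index_drug = idx_drug), as.list(row))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

inflation_factor <- function(tbl, component) {
  tbl$hicp_index[[as.character(tbl$reference_year)]] /
    tbl$hicp_index[[as.character(tbl$source_years[[component]])]]
}

#' Attribute euro costs to counted resource use
#'
#' Prescription cost is the sum of per-class counts times the class unit
#' cost; outpatient cost is visits times specialty points times the
#' orientation value; inpatient cost is admissions times the admission
#' unit cost. Each component is then inflated from its tariff source year
#' to the reference year using the configured price index. Two
#' prescription aggregates are reported: ADHD-related (ADHD-indicated and
#' mental-health classes) and all medication; the headline `total_cost`
#' uses the ADHD-related prescription component, with `total_cost_all`
#' alongside.
#'
#' @param hru Output of [count_hru()].
#' @param tbl A [cost_table()].
#' @return Data frame of per-patient euro costs by component.
#' @export
apply_costs <- function(hru, tbl = cost_table()) {
  classes <- drug_classes()
  missing_cls <- setdiff(classes, names(tbl$drug_unit_costs))
  if (length(missing_cls))
    stop_config("drug_unit_costs",
                paste("is missing classes:",
                      paste(missing_cls, collapse = ", ")))
  missing_sp <- setdiff(specialties(), names(tbl$visit_points))
  if (length(missing_sp))
    stop_config("visit_points",
                paste("is missing specialties:",
                      paste(missing_sp, collapse = ", ")))

  f_drugs <- inflation_factor(tbl, "drugs")
  f_visits <- inflation_factor(tbl, "visits")
  f_adm <- inflation_factor(tbl, "admissions")

  adhd_rel <- c(adhd_classes(), mental_health_classes())
  rx_counts <- as.matrix(hru[paste0("n_rx_", classes)])
  rx_cost_all <- as.numeric(rx_counts %*% tbl$drug_unit_costs[classes])
  rx_cost_adhd <- as.numeric(
    as.matrix(hru[paste0("n_rx_", adhd_rel)]) %*%
      tbl$drug_unit_costs[adhd_rel])
  visit_cost <- as.numeric(
    as.matrix(hru[paste0("n_visits_", specialties())]) %*%
      tbl$visit_points[specialties()]) * tbl$orientation_value
  adm_cost <- hru$n_admissions * tbl$admission_unit_cost

  out <- data.frame(
    patient_id = hru$patient_id,
    index_drug = hru$index_drug,
    prescription_cost = rx_cost_adhd * f_drugs,
    prescription_cost_all = rx_cost_all * f_drugs,
    outpatient_cost = visit_cost * f_visits,
    inpatient_cost = adm_cost * f_adm,
    stringsAsFactors = FALSE)
  out$total_cost <- out$prescription_cost + out$outpatient_cost +
    out$inpatient_cost
  out$total_cost_all <- out$prescription_cost_all + out$outpatient_cost +
    out$inpatient_cost
  out
}

#' Summarize per-patient costs by cohort
#'
#' Median and mean of each cost component per cohort. A component that is
#' zero for more than half the cohort has median 0 by construction; empty
#' cohorts yield `NA` summaries with a flag.
#'
#' @param costs Output of [apply_costs()] (column `index_drug` labels the
#'   cohort).
#' @return Data frame with one row per cohort and component.
#' @export
summarize_costs <- function(costs) {
  comps <- c("prescription_cost", "prescription_cost_all",
             "outpatient_cost", "inpatient_cost", "total_cost",
             "total_cost_all")
  groups <- split(costs, costs$index_drug)
  out <- do.call(rbind, lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    do.call(rbind, lapply(comps, function(cm)
      data.frame(cohort = lab, component = cm, n = nrow(g),
                 median = if (nrow(g)) stats::median(g[[cm]]) else NA_real_,
                 mean = if (nrow(g)) mean(g[[cm]]) else NA_real_,
                 undefined = nrow(g) == 0L,
                 stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out
}
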