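#' Study configuration
#'
#' Bundles the per-stage configurations of the full pipeline: synthetic
#' generation (or the built-in worked-example fixture), cohort selection,
#' the gap rule, the cost table, and matching options. A single global
#' seed deterministically derives every stage seed.
#'
#' @param synth A [synth_config()], or `NULL` when `fixture` is used.
#' @param fixture `NULL`, or `"table4"` to analyse the deterministic
#'   worked-example bundle from [make_table4_fixture()].
#' @param selection A [selection_config()].
#' @param rule A [gap_rule()].
#' @param costs A [cost_table()].
#' @param psm List: `enabled` (run propensity matching and restrict
#'   downstream analyses to the matched sample), `caliper`, and
#'   `scale` (`"probability"` or `"logit"`, the scale the caliper is
#'   applied on).
#' @param seed Global integer seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(synth = synth_config(), fixture = NULL,
                         selection = selection_config(),
                         rule = gap_rule(), costs = cost_table(),
                         psm = list(enabled = TRUE, caliper = 1e-4,
                                    scale = "probability"),
                         seed = 1L) {
  psm$enabled <- isTRUE(psm$enabled %||% TRUE)
  psm$caliper <- psm$caliper %||% 1e-4
  psm$scale <- match.arg(psm$scale %||% "probability",
                         c("probability", "logit"))
  structure(list(synth = synth, fixture = fixture, selection = selection,
                 rule = rule, costs = costs, psm = psm,
                 seed = as.integer(seed)),
            class = "study_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Run the full study pipeline
#'
#' Orchestrates generate (or load fixture) -> cohort selection ->
#' propensity matching -> treatment-pattern classification -> resource
#' counting and costing -> comparison statistics, on an intent-to-treat
#' basis (patients are analysed by index cohort regardless of later
#' switching). Treatment-pattern summaries are computed on the
#' novel-initiator subset; utilization and cost summaries on the full
#' (matched, when matching is enabled) cohorts. All randomness derives
#' from the global seed, so a configuration reproduces its report bundle
#' exactly. When `out_dir` is given, report tables are written as
#' CSV/JSON; a stage failure aborts with the stage name and removes
#' partial outputs.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional output directory.
#' @return A list of report objects (attrition, match diagnostics,
#'   pattern and cost summaries, statistical tests), invisibly when
#'   `out_dir` is given.
#' @export
run_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  outputs <- character(0)
  emit_csv <- function(d, name) {
    if (is.null(out_dir)) return(invisible())
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    outputs <<- c(outputs, p)
  }
  emit_json <- function(x, name) {
    if (is.null(out_dir)) return(invisible())
    p <- file.path(out_dir, name)
    write_json_report(x, p)
    outputs <<- c(outputs, p)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(outputs)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  bundle <- stage("generate", {
    if (!is.null(cfg$fixture)) {
      if (!identical(cfg$fixture, "table4"))
        stop("unknown fixture: ", cfg$fixture)
      make_table4_fixture()
    } else {
      sc <- cfg$synth
      sc$seed <- derive_seed(cfg$seed, 1L)
      generate_bundle(do.call(synth_config, unclass(sc)[names(formals(synth_config))]))
    }
  })
  if (!nrow(bundle$patients)) {
    warning("configuration produced zero patients; emitting empty reports")
    emit_json(list(n_patients = 0L), "attrition.json")
    return(invisible(list(cohorts = build_cohorts(bundle, cfg$selection),
                          n_patients = 0L)))
  }

  cohorts <- stage("select", build_cohorts(bundle, cfg$selection))
  attrition <- attrition_report(cohorts)
  emit_csv(cohorts, "cohorts.csv")
  emit_json(attrition, "attrition.json")

  eligible <- cohorts[cohorts$eligible, , drop = FALSE]
  match_info <- NULL
  analysed <- eligible
  if (cfg$psm$enabled && nrow(eligible) &&
      length(unique(eligible$index_drug)) == 2L) {
    match_info <- stage("match", {
      cov <- encode_covariates(bundle, cohorts, cfg$selection)
      treat <- as.integer(eligible$index_drug == "ATX")
      pm <- fit_propensity(cov, treat)
      score <- pm$fitted
      if (cfg$psm$scale == "logit") score <- stats::qlogis(score)
      names(score) <- eligible$patient_id
      ms <- greedy_match(score[treat == 1L], score[treat == 0L],
                         caliper = cfg$psm$caliper,
                         order_seed = derive_seed(cfg$seed, 2L))
      hl <- hosmer_lemeshow(pm$fitted, treat)
      in_match <- eligible$patient_id %in% c(ms$pairs$treated_id,
                                             ms$pairs$control_id)
      db <- if (any(in_match))
        decile_balance(pm$fitted[in_match], treat[in_match])
      Xnum <- stats::model.matrix(~ . - 1, data = cov)
      rownames(Xnum) <- rownames(cov)
      bal <- balance_report(Xnum, treat, ms)
      list(model = pm, match = ms, hosmer_lemeshow = hl,
           decile_balance = db, balance = bal,
           scores = score, treated = treat)
    })
    emit_csv(match_info$match$pairs, "match_pairs.csv")
    emit_csv(data.frame(patient_id = eligible$patient_id,
                        cohort = eligible$index_drug,
                        score = match_info$model$fitted,
                        matched = eligible$patient_id %in%
                          c(match_info$match$pairs$treated_id,
                            match_info$match$pairs$control_id)),
             "propensity_scores.csv")
    emit_json(list(
      n_pairs = nrow(match_info$match$pairs),
      caliper = cfg$psm$caliper,
      hosmer_lemeshow = match_info$hosmer_lemeshow[c("statistic", "df",
                                                     "p_value")],
      decile_balance = if (!is.null(match_info$decile_balance))
        unclass(match_info$decile_balance)[c("statistic", "df", "p_value")],
      balance = match_info$balance), "balance.json")
    keep <- eligible$patient_id %in% c(match_info$match$pairs$treated_id,
                                       match_info$match$pairs$control_id)
    analysed <- eligible[keep, , drop = FALSE]
  }

  acohorts <- cohorts
  acohorts$eligible <- acohorts$patient_id %in% analysed$patient_id
  patterns <- stage("patterns", evaluate_cohort(bundle, acohorts, cfg$rule))
  emit_csv(patterns, "patterns.csv")

  novel <- patterns[patterns$novel_initiator, , drop = FALSE]
  psum <- stage("patterns", summarize_patterns(novel))
  ptests <- stage("patterns", pattern_tests(novel))
  emit_csv(psum$cohorts, "pattern_summary.csv")
  emit_csv(psum$augment_by_class, "pattern_augment_by_class.csv")
  emit_csv(psum$strata, "pattern_strata.csv")

  hru <- stage("costs", count_hru(bundle, acohorts,
                                  cfg$selection$followup_days))
  costs <- stage("costs", apply_costs(hru, cfg$costs))
  csum <- stage("costs", summarize_costs(costs))
  ctests <- stage("costs", cost_tests(hru, costs))
  emit_csv(hru, "hru.csv")
  emit_csv(costs, "costs.csv")
  emit_csv(csum, "cost_summary.csv")

  emit_json(list(seed = cfg$seed, pattern_tests = ptests,
                 cost_tests = ctests), "stats_report.json")

  invisible(list(bundle = bundle, cohorts = cohorts, attrition = attrition,
                 match = match_info, patterns = patterns,
                 pattern_summary = psum, pattern_tests = ptests,
                 hru = hru, costs = costs, cost_summary = csum,
                 cost_tests = ctests))
}

# contingency/log-rank comparisons for the pattern analogue table
pattern_tests <- function(novel) {
  arms <- split(novel, novel$index_drug)
  if (length(arms) != 2L || any(vapply(arms, nrow, integer(1)) == 0L))
    return(list(note = "tests require two non-empty cohorts"))
  g1 <- arms[[1]]; g2 <- arms[[2]]
  two_prop <- function(e1, e2, n1 = nrow(g1), n2 = nrow(g2)) {
    if (e1 + e2 == 0L || (e1 == n1 && e2 == n2)) return(NULL)
    unclass(chi2_2x2(e1, n1 - e1, e2, n2 - e2))[c("statistic", "df",
                                                  "p_value", "method")]
  }
  d1 <- sum(g1$discontinued | g1$switched)
  d2 <- sum(g2$discontinued | g2$switched)
  strata <- table(novel$index_drug,
                  factor(novel$first_change_stratum,
                         levels = c("0-90", "91-180", "181-360")))
  strata_test <- if (all(rowSums(strata) > 0))
    unclass(chi2_rxc(strata))[c("statistic", "df", "p_value", "method")]
  lr <- log_rank_test(novel$persistence_days,
                      novel$discontinued | novel$switched | novel$augmented,
                      novel$index_drug)
  list(switch = two_prop(sum(g1$switched), sum(g2$switched)),
       restart = if (d1 > 0 && d2 > 0)
         two_prop(sum(g1$restarted), sum(g2$restarted), d1, d2),
       augment = two_prop(sum(g1$augmented), sum(g2$augmented)),
       augment_antipsychotic = two_prop(
         sum(g1$augmented & g1$augment_class == "antipsychotic",
             na.rm = TRUE),
         sum(g2$augmented & g2$augment_class == "antipsychotic",
             na.rm = TRUE)),
       augment_sa_mph = two_prop(
         sum(g1$augmented & g1$augment_class == "SA_MPH", na.rm = TRUE),
         sum(g2$augmented & g2$augment_class == "SA_MPH", na.rm = TRUE)),
       first_change_strata = strata_test,
       persistence_logrank = unclass(lr)[c("statistic", "df", "p_value",
                                           "method")],
       persistence_t = if (nrow(g1) >= 2L && nrow(g2) >= 2L &&
                           (stats::sd(g1$persistence_days) > 0 ||
                              stats::sd(g2$persistence_days) > 0))
         unclass(t_test(g1$persistence_days, g2$persistence_days))[
           c("statistic", "df", "p_value", "method")])
}

# rank-sum comparisons for the utilization/cost analogue table
cost_tests <- function(hru, costs) {
  if (length(unique(hru$index_drug)) != 2L)
    return(list(note = "tests require two non-empty cohorts"))
  by_arm <- function(d, col) split(d[[col]], d$index_drug)
  rs <- function(d, col) {
    s <- by_arm(d, col)
    unclass(rank_sum_test(s[[1]], s[[2]]))[c("statistic", "df", "p_value",
                                             "method")]
  }
  list(n_rx_total = rs(hru, "n_rx_total"),
       n_rx_index = rs(hru, "n_rx_index"),
       n_visits_total = rs(hru, "n_visits_total"),
       total_cost = rs(costs, "total_cost"),
       prescription_cost = rs(costs, "prescription_cost"),
       outpatient_cost = rs(costs, "outpatient_cost"))
}
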