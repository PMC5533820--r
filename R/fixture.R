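# Deterministic worked-example fixture ---------------------------------------
#
# Builds, with no randomness, a bundle of 974 eligible novel initiators
# (486 ATX-indexed, 488 LA-MPH-indexed) whose prescription timelines, when
# run through the pattern engine under the default gap rule, reproduce a
# published set of treatment-pattern counts exactly:
#   switchers               43 vs  27
#   discontinuers/switchers 126 vs 181
#   restarters               87 vs 171
#   augmenters (any)         83 vs  89
#     antipsychotic          37 vs  16
#     short-acting MPH       23 vs  64
#   first-change strata  80/26/20 vs 75/29/12  (0-90 / 91-180 / 181-360 d)
#
# Timelines are constructed backwards from the target labels. Every
# patient indexes on 2008-08-01 and every engineered gap starts on or
# before day 243, so the first 30 uncovered days always precede May and
# the standard 30-day rule applies throughout (no holiday interaction).
# Archetypes (day offsets from index, default 60-day fills unless noted):
#   persister     fills at 0, 60, ..., 360       -> no events
#   switcher(c)   fills at 0 and 1 summing to c days of supply, then a
#                 non-index fill (60 d) at day c  -> switch on day c,
#                 discontinuation on day c+30; restarters refill index
#                 drug on day c+40
#   augmenter(c)  fills at 0 and 1 summing to c+30 days, a non-index fill
#                 (30 d) at day c fully inside coverage -> augmentation on
#                 day c, discontinuation on day c+60; restarters refill on
#                 day c+69+... (40 days into the gap)
#   discontinuer  fills at 0 and 1 (30 d each) -> discontinuation day 90;
#                 restart fill on day 130

fixture_index_date <- function() as.Date("2008-08-01")

fx_rx <- function(id, day, drug, supply) {
  data.frame(patient_id = id, date = fixture_index_date() + day,
             drug_class = drug, supply_days = as.integer(supply),
             stringsAsFactors = FALSE)
}

fx_persister <- function(id, drug) {
  fx_rx(id, seq(0L, 360L, by = 60L), drug, 60L)
}

fx_switcher <- function(id, drug, c_day, switch_class, restart) {
  a <- c_day %/% 2L
  rx <- rbind(fx_rx(id, 0L, drug, a), fx_rx(id, 1L, drug, c_day - a),
              fx_rx(id, c_day, switch_class, 60L))
  if (restart) rx <- rbind(rx, fx_rx(id, c_day + 40L, drug, 60L))
  rx
}

fx_augmenter <- function(id, drug, c_day, augment_class, restart) {
  tot <- c_day + 30L
  a <- tot %/% 2L
  rx <- rbind(fx_rx(id, 0L, drug, a), fx_rx(id, 1L, drug, tot - a),
              fx_rx(id, c_day, augment_class, 30L))
  if (restart) rx <- rbind(rx, fx_rx(id, tot + 40L, drug, 60L))
  rx
}

fx_discontinuer <- function(id, drug, restart) {
  rx <- rbind(fx_rx(id, 0L, drug, 30L), fx_rx(id, 1L, drug, 30L))
  if (restart) rx <- rbind(rx, fx_rx(id, 130L, drug, 60L))
  rx
}

# cycle the k-th value (1-based) out of a candidate pool
fx_cycle <- function(pool, k) pool[((k - 1L) %% length(pool)) + 1L]

# first-change day pools per stratum; gap starts stay <= day 243
fx_switch_days <- list(`1` = c(40L, 50L, 60L, 70L, 80L, 90L),
                       `2` = c(91L, 110L, 135L, 160L, 180L),
                       `3` = c(181L, 200L, 220L, 243L))
fx_augment_days <- list(`1` = c(35L, 45L, 55L, 65L, 80L, 90L),
                        `2` = c(91L, 115L, 140L, 170L, 180L),
                        `3` = c(181L, 190L, 200L, 213L))

#' Deterministic treatment-pattern worked-example bundle
#'
#' Constructs, without randomness, an EMR bundle of 974 eligible novel
#' initiators (486 atomoxetine-indexed, 488 long-acting
#' methylphenidate-indexed) whose timelines are engineered backwards from
#' target event labels, so that running [build_cohorts()] and
#' [evaluate_cohort()] under default rules reproduces a known table of
#' switch, restart, augmentation and time-to-first-change counts exactly
#' (43 vs 27 switchers, 126 vs 181 discontinuers-or-switchers, 87 vs 171
#' restarters, 83 vs 89 augmenters of which 37 vs 16 antipsychotic and
#' 23 vs 64 short-acting methylphenidate, and 80/26/20 vs 75/29/12
#' first-change strata). All patients share the index date 2008-08-01 and
#' pass every inclusion rule.
#'
#' @return An EMR bundle (see [generate_bundle()]).
#' @examples
#' fx <- make_table4_fixture()
#' table(build_cohorts(fx)$index_drug)
#' @export
make_table4_fixture <- function() {
  rx <- list()
  pts <- list()
  add_patient <- function(id) {
    k <- length(pts) + 1L
    pts[[k]] <<- data.frame(
      patient_id = id,
      sex = if (k %% 5L == 0L) "female" else "male",
      age_at_index = 6L + (k %% 12L),
      region = regions()[(k %% 8L) + 1L],
      insurance = "dependant",
      practice_specialty = specialties()[c(2L, 2L, 2L, 3L)[(k %% 4L) + 1L]],
      comorbidity_flags = if (k %% 7L == 0L) "learning_difficulties" else "",
      adhd_dx_pre_index = TRUE,
      stringsAsFactors = FALSE)
  }
  add_rx <- function(d) rx[[length(rx) + 1L]] <<- d

  build_arm <- function(prefix, drug, n_total,
                        sw_strata, sw_classes, sw_restarts,
                        aug_strata, aug_classes, aug_restarts,
                        n_pure_disc, pure_disc_restarts) {
    serial <- 0L
    next_id <- function() {
      serial <<- serial + 1L
      sprintf("%s%04d", prefix, serial)
    }
    # switchers: strata counts, classes cycled, first `sw_restarts` restart
    si <- 0L
    for (stratum in names(sw_strata)) {
      for (j in seq_len(sw_strata[[stratum]])) {
        si <- si + 1L
        id <- next_id(); add_patient(id)
        add_rx(fx_switcher(id, drug,
                           fx_cycle(fx_switch_days[[stratum]], j),
                           fx_cycle(sw_classes, si),
                           restart = si <= sw_restarts))
      }
    }
    # augmenters: classes assigned in blocks, first `aug_restarts` restart
    ai <- 0L
    class_seq <- rep(names(aug_classes), times = unlist(aug_classes))
    for (stratum in names(aug_strata)) {
      for (j in seq_len(aug_strata[[stratum]])) {
        ai <- ai + 1L
        id <- next_id(); add_patient(id)
        add_rx(fx_augmenter(id, drug,
                            fx_cycle(fx_augment_days[[stratum]], j),
                            class_seq[ai],
                            restart = ai <= aug_restarts))
      }
    }
    for (j in seq_len(n_pure_disc)) {
      id <- next_id(); add_patient(id)
      add_rx(fx_discontinuer(id, drug, restart = j <= pure_disc_restarts))
    }
    n_persist <- n_total - si - ai - n_pure_disc
    for (j in seq_len(n_persist)) {
      id <- next_id(); add_patient(id)
      add_rx(fx_persister(id, drug))
    }
  }

  build_arm("A", "ATX", 486L,
            sw_strata = list(`1` = 28L, `2` = 8L, `3` = 7L),
            sw_classes = c("LA_MPH", "LA_MPH", "SA_MPH",
                           "antidepressant_mood"),
            sw_restarts = 30L,
            aug_strata = list(`1` = 52L, `2` = 18L, `3` = 13L),
            aug_classes = list(antipsychotic = 37L, SA_MPH = 23L,
                               tranquilizer = 23L),
            aug_restarts = 57L,
            n_pure_disc = 0L, pure_disc_restarts = 0L)
  build_arm("L", "LA_MPH", 488L,
            sw_strata = list(`1` = 18L, `2` = 5L, `3` = 4L),
            sw_classes = c("SA_MPH", "antidepressant_mood"),
            sw_restarts = 17L,
            aug_strata = list(`1` = 57L, `2` = 24L, `3` = 8L),
            aug_classes = list(antipsychotic = 16L, SA_MPH = 64L,
                               tranquilizer = 9L),
            aug_restarts = 89L,
            n_pure_disc = 65L, pure_disc_restarts = 65L)

  patients <- do.call(rbind, pts)
  prescriptions <- do.call(rbind, rx)
  visits <- rbind(
    data.frame(patient_id = patients$patient_id,
               date = fixture_index_date() - 100L,
               specialty = patients$practice_specialty, sick_note = FALSE,
               stringsAsFactors = FALSE),
    data.frame(patient_id = patients$patient_id,
               date = fixture_index_date() + 50L,
               specialty = patients$practice_specialty, sick_note = FALSE,
               stringsAsFactors = FALSE))
  bundle <- list(patients = patients, prescriptions = prescriptions,
                 visits = visits, admissions = empty_bundle()$admissions)
  clip_bundle(bundle, as.Date(c("2005-01-01", "2011-12-31")))
}
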