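idx_at <- function(date, drug = "ATX") {
  list(patient_id = "P1", index_date = as.Date(date), index_drug = drug)
}

fills_days <- function(index_date, days, supply, drug = "ATX") {
  data.frame(patient_id = "P1", date = as.Date(index_date) + days,
             drug_class = drug, supply_days = as.integer(supply),
             stringsAsFactors = FALSE)
}

test_that("timeline construction stockpiles, merges and truncates", {
  rule <- gap_rule()
  idx <- idx_at("2008-02-01")

  tl <- build_timeline(fills_days(idx$index_date, 0, 60), idx, rule)
  expect_equal(tl$intervals, data.frame(start = 0L, end = 59L))

  # early refill extends coverage forward: the day-30 refill starts
  # contributing on day 60, so 120 supplied days run uninterrupted
  tl <- build_timeline(fills_days(idx$index_date, c(0, 30), c(60, 60)),
                       idx, rule)
  expect_equal(tl$intervals, data.frame(start = 0L, end = 119L))

  # without stockpiling the overlapping supply is wasted
  tl <- build_timeline(fills_days(idx$index_date, c(0, 30), c(60, 60)),
                       idx, gap_rule(stockpile = FALSE))
  expect_equal(tl$intervals, data.frame(start = 0L, end = 89L))
  tl <- build_timeline(fills_days(idx$index_date, c(0, 10), c(30, 15)),
                       idx, gap_rule(stockpile = FALSE))
  expect_equal(tl$intervals, data.frame(start = 0L, end = 29L))

  # fill past follow-up end contributes nothing
  tl <- build_timeline(fills_days(idx$index_date, c(0, 400), c(60, 60)),
                       idx, rule)
  expect_equal(tl$intervals, data.frame(start = 0L, end = 59L))

  expect_error(build_timeline(fills_days(idx$index_date, 5, 60), idx, rule),
               "index date")
})

test_that("discontinuation detection applies the 30-day and holiday rules", {
  rule <- gap_rule()

  # continuous coverage to follow-up end: no event
  idx <- idx_at("2008-02-01")
  tl <- build_timeline(fills_days(idx$index_date, c(0, 180), c(182, 185)),
                       idx, rule)
  expect_null(detect_discontinuation(tl, rule))

  # 40-day gap starting 1 February: event, dated 30 days into the gap
  idx <- idx_at("2008-11-01")  # day 92 = 2009-02-01
  tl <- build_timeline(fills_days(idx$index_date, c(0, 132), c(92, 233)),
                       idx, rule)
  ev <- detect_discontinuation(tl, rule)
  expect_identical(ev$gap_start, 92L)
  expect_identical(ev$disc_day, 122L)
  expect_identical(ev$threshold, 30L)

  # 45-day gap entirely inside June-July is a sanctioned drug holiday
  idx <- idx_at("2008-12-01")  # day 182 = 2009-06-01
  tl <- build_timeline(fills_days(idx$index_date, c(0, 227), c(182, 138)),
                       idx, rule)
  expect_null(detect_discontinuation(tl, rule))

  # the same gap in winter is a discontinuation
  idx <- idx_at("2008-02-01")
  tl <- build_timeline(fills_days(idx$index_date, c(0, 227), c(182, 138)),
                       idx, rule)
  expect_identical(detect_discontinuation(tl, rule)$disc_day, 212L)

  # a 95-day summer gap exceeds even the holiday allowance
  idx <- idx_at("2008-12-01")
  tl <- build_timeline(fills_days(idx$index_date, c(0, 277), c(182, 88)),
                       idx, rule)
  ev <- detect_discontinuation(tl, rule)
  expect_identical(ev$threshold, 90L)
  expect_identical(ev$disc_day, 272L)
})

test_that("switch classification honours window, supply and class rules", {
  rule <- gap_rule()
  idx <- idx_at("2008-02-01")
  tl <- build_timeline(fills_days(idx$index_date, 0, 60), idx, rule)
  disc <- detect_discontinuation(tl, rule)
  expect_identical(disc$gap_start, 60L)

  nf <- function(day, class = "LA_MPH", supply = 60L)
    data.frame(day = day, drug_class = class, supply_days = supply,
               stringsAsFactors = FALSE)

  sw <- classify_switch(disc, nf(69), rule, "ATX")
  expect_identical(sw$switch_day, 69L)
  expect_identical(sw$switch_to_class, "LA_MPH")

  expect_null(classify_switch(disc, nf(105), rule, "ATX"))       # window
  expect_null(classify_switch(disc, nf(69, supply = 14L), rule, "ATX"))
  expect_null(classify_switch(disc, nf(69, class = "other"), rule, "ATX"))
  expect_null(classify_switch(NULL, nf(69), rule, "ATX"))
  # earliest qualifying fill wins
  sw <- classify_switch(disc, rbind(nf(80), nf(65, "SA_MPH")), rule, "ATX")
  expect_identical(sw$switch_to_class, "SA_MPH")
})

test_that("restart detection is bounded by follow-up", {
  expect_identical(detect_restart(c(0L, 110L), 90L, 365L)$restart_day, 110L)
  expect_null(detect_restart(c(0L, 60L), 90L, 365L))
  expect_null(detect_restart(c(0L, 365L), 90L, 365L))  # day after end
  expect_identical(detect_restart(c(0L, 364L), 90L, 365L)$restart_day, 364L)
})

test_that("augmentation requires 30 distinct days of concurrent supply", {
  rule <- gap_rule()
  idx <- idx_at("2008-02-01")
  tl <- build_timeline(fills_days(idx$index_date, c(0, 60), c(60, 60)),
                       idx, rule)
  nf <- function(day, supply, class = "SA_MPH")
    data.frame(day = day, drug_class = class, supply_days = supply,
               stringsAsFactors = FALSE)

  aug <- detect_augmentation(tl, nf(10, 60), rule, "ATX")
  expect_identical(aug$augment_day, 10L)
  expect_identical(aug$augment_class, "SA_MPH")

  # 29 overlapping days only (supply runs past coverage end)
  expect_null(detect_augmentation(tl, nf(91, 60), rule, "ATX"))
  expect_identical(detect_augmentation(tl, nf(90, 60), rule,
                                       "ATX")$augment_day, 90L)
  expect_null(detect_augmentation(tl, nf(10, 29), rule, "ATX"))
  expect_null(detect_augmentation(tl, nf(10, 60)[0, ], rule, "ATX"))
})

test_that("per-patient composition matches the stated persistence rule", {
  rule <- gap_rule()
  d0 <- as.Date("2008-02-01")
  idx <- idx_at(d0)

  # full coverage, no events: censored at 365
  r <- evaluate_patient(fills_days(d0, c(0, 180), c(182, 185)), idx, rule)
  expect_identical(r$persistence_days, 365L)
  expect_false(r$discontinued || r$switched || r$augmented)

  # augmentation on day 100 while covered
  f <- rbind(fills_days(d0, c(0, 180), c(182, 185)),
             fills_days(d0, 100, 60, drug = "SA_MPH"))
  r <- evaluate_patient(f, idx, rule)
  expect_true(r$augmented)
  expect_identical(r$persistence_days, 100L)
  expect_identical(r$first_change_stratum, "91-180")

  # discontinuation after a 30-day gap starting day 60
  r <- evaluate_patient(fills_days(d0, 0, 60), idx, rule)
  expect_true(r$discontinued)
  expect_identical(r$discontinuation_day, 90L)
  expect_identical(r$persistence_days, 90L)
  # the alternative convention stops persistence at the end of supply
  r2 <- evaluate_patient(fills_days(d0, 0, 60), idx,
                         gap_rule(persistence_includes_gap = FALSE))
  expect_identical(r2$persistence_days, 60L)
})

test_that("engine equals the day-grid oracle on random timelines", {
  set.seed(404)
  rule <- gap_rule()
  for (rep in 1:400) {
    case <- random_patient_fills()
    got <- run_engine_on(case, rule)
    want <- oracle_patterns(case$fills, case$index_date, case$index_drug)
    for (f in names(want)) {
      expect_identical(unname(got[[f]]), unname(want[[f]]),
                       label = sprintf("rep %d field %s (engine %s)",
                                       rep, f, format(got[[f]])),
                       expected.label = format(want[[f]]))
    }
  }
})

test_that("persistence is monotone under fill removal and bounded by follow-up", {
  set.seed(77)
  # monotonicity concerns the index-therapy episode itself: it holds under
  # a single gap threshold and without augmentation (a removed fill can
  # shift a gap into the tolerated May-July window, and shrinking coverage
  # can dissolve an augmentation overlap, both of which legitimately move
  # the episode end later), so those two interactions are excluded here
  rule <- gap_rule(holiday_gap_days = 30L)
  for (rep in 1:60) {
    case <- random_patient_fills()
    case$fills <- case$fills[case$fills$drug_class == case$index_drug, ,
                             drop = FALSE]
    base <- run_engine_on(case, rule)
    expect_lte(base$persistence_days, 365L)
    expect_gte(base$persistence_days, 1L)
    # drop one non-first index fill (keeps the timeline valid)
    idx_rows <- which(case$fills$drug_class == case$index_drug &
                        case$fills$day > 0)
    if (length(idx_rows)) {
      case2 <- case
      drop_row <- idx_rows[sample.int(length(idx_rows), 1)]
      case2$fills <- case2$fills[-drop_row, ]
      expect_lte(run_engine_on(case2, rule)$persistence_days,
                 base$persistence_days)
    }
  }
})

test_that("a gap tolerated under the standard rule is never an event under the holiday rule", {
  set.seed(88)
  strict <- gap_rule(holiday_gap_days = 30L)  # holiday allowance disabled
  lenient <- gap_rule()
  for (rep in 1:60) {
    case <- random_patient_fills()
    if (!run_engine_on(case, strict)$discontinued)
      expect_false(run_engine_on(case, lenient)$discontinued)
  }
})

test_that("pattern summaries report undefined percentages on empty denominators", {
  s <- summarize_patterns(evaluate_cohort(
    generate_bundle(synth_config(n_patients = 0)),
    build_cohorts(generate_bundle(synth_config(n_patients = 0)))))
  expect_identical(nrow(s$cohorts), 0L)

  # one persister only: no discontinuers, restart percentage undefined
  d0 <- as.Date("2008-02-01")
  r <- evaluate_patient(fills_days(d0, c(0, 180), c(182, 185)),
                        idx_at(d0), gap_rule())
  r$novel_initiator <- TRUE
  s <- summarize_patterns(r)
  expect_identical(s$cohorts$n_disc_or_switch, 0L)
  expect_true(is.na(s$cohorts$pct_restart))
})
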