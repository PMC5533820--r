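mk_fills <- function(id = "P1", dates, classes, supply = 60L) {
  data.frame(patient_id = id, date = as.Date(dates), drug_class = classes,
             supply_days = supply, stringsAsFactors = FALSE)
}

mk_patient <- function(id = "P1", age = 10L, adhd = TRUE) {
  data.frame(patient_id = id, sex = "male", age_at_index = age,
             region = "R1", insurance = "dependant",
             practice_specialty = "paediatrics", comorbidity_flags = "",
             adhd_dx_pre_index = adhd, stringsAsFactors = FALSE)
}

mk_visits <- function(id = "P1", dates) {
  data.frame(patient_id = id, date = as.Date(dates),
             specialty = "paediatrics", sick_note = FALSE,
             stringsAsFactors = FALSE)
}

test_that("index assignment follows the preferential-ATX rule", {
  cfg <- selection_config()
  # single LA-MPH candidate
  f <- mk_fills(dates = "2008-03-01", classes = "LA_MPH")
  idx <- assign_index(f, cfg)
  expect_identical(idx$index_drug, "LA_MPH")
  expect_identical(idx$index_date, as.Date("2008-03-01"))

  # both drugs present as monotherapy: ATX wins even when LA-MPH is earlier
  f <- mk_fills(dates = c("2007-01-10", "2008-06-01"),
                classes = c("LA_MPH", "ATX"))
  idx <- assign_index(f, cfg)
  expect_identical(idx$index_drug, "ATX")
  expect_identical(idx$index_date, as.Date("2008-06-01"))

  # same-day co-prescription is not monotherapy for either drug
  f <- mk_fills(dates = c("2008-06-01", "2008-06-01", "2008-09-01"),
                classes = c("LA_MPH", "ATX", "LA_MPH"))
  idx <- assign_index(f, cfg)
  expect_identical(idx$index_drug, "LA_MPH")
  expect_identical(idx$index_date, as.Date("2008-09-01"))

  # only fills outside the window
  f <- mk_fills(dates = c("2005-06-01", "2011-06-01"),
                classes = c("ATX", "ATX"))
  expect_null(assign_index(f, cfg))

  expect_error(assign_index(mk_fills(id = c("P1", "P2"),
                                     dates = c("2008-01-01", "2008-01-02"),
                                     classes = c("ATX", "ATX")), cfg),
               "single patient")
})

test_that("exclusion rules fire with labelled reasons and respect the 60-day boundary", {
  cfg <- selection_config()
  pat <- mk_patient()
  vis <- mk_visits(dates = c("2008-01-01", "2008-09-01"))
  d0 <- as.Date("2008-06-01")

  base <- mk_fills(dates = c(d0, d0 + 30), classes = c("ATX", "ATX"))
  idx <- assign_index(base, cfg)
  out <- apply_exclusions(pat, base, vis, idx, cfg)
  expect_true(out$eligible)
  expect_length(out$exclusion_reasons, 0)

  # SA-MPH 30 days before index
  f <- rbind(base, mk_fills(dates = d0 - 30, classes = "SA_MPH"))
  out <- apply_exclusions(pat, f, vis, assign_index(f, cfg), cfg)
  expect_false(out$eligible)
  expect_true("SA_MPH_within_60d" %in% out$exclusion_reasons)

  # other study drug 90 days pre-index does not trigger the co-exposure rule
  f <- rbind(base, mk_fills(dates = d0 - 90, classes = "LA_MPH"))
  out <- apply_exclusions(pat, f, vis, assign_index(f, cfg), cfg)
  expect_true(out$eligible)
  # ... but at 60 days it does
  f <- rbind(base, mk_fills(dates = d0 - 60, classes = "LA_MPH"))
  out <- apply_exclusions(pat, f, vis, assign_index(f, cfg), cfg)
  expect_true("both_ATX_LA_MPH_within_60d" %in% out$exclusion_reasons)

  # the index fill alone does not satisfy the follow-up fill requirement
  f <- mk_fills(dates = d0, classes = "ATX")
  out <- apply_exclusions(pat, f, vis, assign_index(f, cfg), cfg)
  expect_true("no_followup_index_fill" %in% out$exclusion_reasons)

  # age outside range
  out <- apply_exclusions(mk_patient(age = 19L), base, vis,
                          assign_index(base, cfg), cfg)
  expect_true("age_outside_range" %in% out$exclusion_reasons)
})

test_that("novel-initiator flag uses the half-open 365-day baseline window", {
  cfg <- selection_config()
  d0 <- as.Date("2008-06-01")
  idx <- list(patient_id = "P1", index_date = d0, index_drug = "ATX")

  f <- mk_fills(dates = c(d0, d0 + 30), classes = c("ATX", "ATX"))
  expect_true(flag_novel_initiator(f, idx, cfg))

  f2 <- rbind(f, mk_fills(dates = d0 - 200, classes = "SA_MPH"))
  expect_false(flag_novel_initiator(f2, idx, cfg))

  # exactly 366 days pre-index falls outside the baseline window
  f3 <- rbind(f, mk_fills(dates = d0 - 366, classes = "LA_MPH"))
  expect_true(flag_novel_initiator(f3, idx, cfg))
  f4 <- rbind(f, mk_fills(dates = d0 - 365, classes = "LA_MPH"))
  expect_false(flag_novel_initiator(f4, idx, cfg))
})

test_that("build_cohorts handles empty and uniformly excluded bundles", {
  empty <- generate_bundle(synth_config(n_patients = 0))
  expect_identical(nrow(build_cohorts(empty)), 0L)

  fx <- make_table4_fixture()
  # give every patient an SA-MPH fill on the index date
  sa <- data.frame(patient_id = fx$patients$patient_id,
                   date = as.Date("2008-08-01"), drug_class = "SA_MPH",
                   supply_days = 30L, stringsAsFactors = FALSE)
  fx$prescriptions <- rbind(fx$prescriptions, sa)
  co <- build_cohorts(fx)
  expect_identical(sum(co$eligible), 0L)
})

test_that("cohorts are mutually exclusive and adding exclusion records is monotone", {
  b <- generate_bundle(synth_config(n_patients = 150, seed = 5))
  co <- build_cohorts(b)
  expect_identical(anyDuplicated(co$patient_id), 0L)
  el <- co[co$eligible, ]
  expect_true(all(el$index_drug %in% c("ATX", "LA_MPH")))

  # adding an SA-MPH fill at index can never turn an ineligible patient
  # eligible, and flips eligible patients to excluded
  sa <- data.frame(patient_id = b$patients$patient_id,
                   date = co$index_date[match(b$patients$patient_id,
                                              co$patient_id)],
                   drug_class = "SA_MPH", supply_days = 30L,
                   stringsAsFactors = FALSE)
  sa <- sa[!is.na(sa$date), ]
  b2 <- b
  b2$prescriptions <- rbind(b2$prescriptions, sa)
  co2 <- build_cohorts(b2)
  was_inel <- co$patient_id[!co$eligible]
  expect_false(any(co2$eligible[co2$patient_id %in% was_inel]))
})

test_that("eligibility equals a rule-by-rule brute-force re-check on random bundles", {
  b <- generate_bundle(synth_config(n_patients = 200, seed = 9))
  cfg <- selection_config()
  co <- build_cohorts(b, cfg)
  rx_s <- split(b$prescriptions, b$prescriptions$patient_id)
  vi_s <- split(b$visits, b$visits$patient_id)
  for (i in seq_len(nrow(b$patients))) {
    p <- b$patients[i, ]
    o <- oracle_eligibility(p, rx_s[[p$patient_id]],
                            vi_s[[p$patient_id]], cfg)
    row <- co[co$patient_id == p$patient_id, ]
    if (!o$indexed) {
      expect_false(row$eligible)
    } else {
      expect_identical(row$eligible, o$eligible)
      expect_identical(row$index_drug, o$index_drug)
      expect_identical(row$index_date, o$index_date)
    }
  }
})

test_that("attrition report counts reasons in rule order", {
  b <- generate_bundle(synth_config(n_patients = 250, seed = 13))
  co <- build_cohorts(b)
  rep <- attrition_report(co)
  expect_identical(rep$n_patients, 250L)
  expect_identical(rep$n_eligible, sum(co$eligible))
  expect_identical(sum(unlist(rep$exclusion_counts) > 0) >= 1, TRUE)
})
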