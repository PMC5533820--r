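fixture_hru_bundle <- function() {
  d0 <- as.Date("2008-06-01")
  pats <- data.frame(patient_id = c("P1", "P2"), sex = "male",
                     age_at_index = 10L, region = "R1",
                     insurance = "dependant",
                     practice_specialty = "paediatrics",
                     comorbidity_flags = "", adhd_dx_pre_index = TRUE,
                     stringsAsFactors = FALSE)
  rx <- rbind(
    data.frame(patient_id = "P1", date = d0 + seq(0, 350, by = 50),
               drug_class = "ATX", supply_days = 60L,
               stringsAsFactors = FALSE),          # 8 fills, 1 at index
    data.frame(patient_id = "P1", date = d0 + seq(30, 230, by = 50),
               drug_class = "SA_MPH", supply_days = 30L,
               stringsAsFactors = FALSE),          # 5 fills
    data.frame(patient_id = "P2", date = c(d0, d0 + 100),
               drug_class = "LA_MPH", supply_days = 60L,
               stringsAsFactors = FALSE))
  vis <- rbind(
    data.frame(patient_id = "P1", date = d0 + c(-100, 40, 80, 120),
               specialty = "paediatrics",
               sick_note = c(FALSE, TRUE, FALSE, FALSE),
               stringsAsFactors = FALSE),
    data.frame(patient_id = "P2", date = d0 + c(-50, 60),
               specialty = "psychiatry", sick_note = FALSE,
               stringsAsFactors = FALSE))
  adm <- data.frame(patient_id = "P1", date = d0 + 200,
                    stringsAsFactors = FALSE)
  list(patients = pats, prescriptions = rx, visits = vis, admissions = adm)
}

test_that("follow-up resource counts tally exactly", {
  b <- fixture_hru_bundle()
  co <- build_cohorts(b)
  expect_true(all(co$eligible))
  hru <- count_hru(b, co)
  p1 <- hru[hru$patient_id == "P1", ]
  expect_identical(p1$n_rx_index, 7L)       # index-date fill not counted
  expect_identical(p1$n_rx_SA_MPH, 5L)
  expect_identical(p1$n_rx_total, 12L)
  expect_identical(p1$n_visits_paediatrics, 3L)
  expect_identical(p1$n_admissions, 1L)
  expect_identical(p1$n_sick_notes, 1L)
  # component prescription counts sum to the total
  expect_identical(p1$n_rx_index + p1$n_rx_other_adhd + p1$n_rx_other_mh +
                     p1$n_rx_other, p1$n_rx_total)
})

test_that("counts equal an independent filter-and-count oracle on random records", {
  b <- generate_bundle(synth_config(n_patients = 80, seed = 21))
  co <- build_cohorts(b)
  hru <- count_hru(b, co)
  el <- co[co$eligible, ]
  for (i in seq_len(nrow(el))) {
    id <- el$patient_id[i]; d0 <- as.Date(el$index_date[i])
    rx <- b$prescriptions
    in_fu <- as.Date(rx$date) > d0 & as.Date(rx$date) <= d0 + 365 &
      rx$patient_id == id
    expect_identical(hru$n_rx_total[hru$patient_id == id], sum(in_fu))
    vi <- b$visits
    expect_identical(hru$n_visits_total[hru$patient_id == id],
                     sum(as.Date(vi$date) > d0 & as.Date(vi$date) <= d0 + 365 &
                           vi$patient_id == id))
  }
})

test_that("cost attribution is linear arithmetic at the configured rates", {
  b <- fixture_hru_bundle()
  co <- build_cohorts(b)
  hru <- count_hru(b, co)
  flat <- cost_table(hicp_index = c(`2011` = 100, `2012` = 100))
  costs <- apply_costs(hru, flat)
  p2 <- costs[costs$patient_id == "P2", ]
  # one LA-MPH follow-up fill at 45 euros, one psychiatry visit at
  # 500 points x 0.035 euro/point = 17.50 euros
  expect_equal(p2$prescription_cost, 45)
  expect_equal(p2$outpatient_cost, 500 * 0.035)
  expect_equal(p2$inpatient_cost, 0)
  expect_equal(p2$total_cost, 45 + 17.5)

  # one visit at 300 configured points costs 10.50 euros before inflation
  expect_equal(300 * flat$orientation_value, 10.5)

  # conservation and linearity
  expect_equal(costs$total_cost,
               costs$prescription_cost + costs$outpatient_cost +
                 costs$inpatient_cost)
  hru2 <- hru
  ncols <- grep("^n_", names(hru2))
  hru2[ncols] <- lapply(hru2[ncols], function(x) 2L * x)
  expect_equal(apply_costs(hru2, flat)$total_cost_all,
               2 * costs$total_cost_all)
})

test_that("inflation adjustment scales by the index ratio and is neutral when flat", {
  b <- fixture_hru_bundle()
  hru <- count_hru(b, build_cohorts(b))
  flat <- cost_table(hicp_index = c(`2011` = 100, `2012` = 100))
  infl <- cost_table(hicp_index = c(`2011` = 98, `2012` = 100))
  c_flat <- apply_costs(hru, flat)
  c_infl <- apply_costs(hru, infl)
  expect_equal(c_infl$prescription_cost, c_flat$prescription_cost * 100 / 98)
  expect_equal(c_infl$outpatient_cost, c_flat$outpatient_cost * 100 / 98)
  expect_equal(c_infl$inpatient_cost, c_flat$inpatient_cost)  # 2012 tariff
})

test_that("missing tariff entries raise configuration errors naming the class", {
  b <- fixture_hru_bundle()
  hru <- count_hru(b, build_cohorts(b))
  tbl <- cost_table()
  tbl$drug_unit_costs <- tbl$drug_unit_costs[names(tbl$drug_unit_costs)
                                             != "SA_MPH"]
  expect_error(apply_costs(hru, tbl), "SA_MPH")
})

test_that("cost summaries use order statistics with majority-zero medians", {
  costs <- data.frame(
    patient_id = sprintf("P%d", 1:7),
    index_drug = c(rep("ATX", 4), rep("LA_MPH", 3)),
    prescription_cost = c(10, 20, 30, 40, 5, 5, 5),
    prescription_cost_all = c(10, 20, 30, 40, 5, 5, 5),
    outpatient_cost = 0, inpatient_cost = c(0, 0, 0, 1000, 0, 0, 0),
    stringsAsFactors = FALSE)
  costs$total_cost <- costs$prescription_cost + costs$outpatient_cost +
    costs$inpatient_cost
  costs$total_cost_all <- costs$total_cost
  s <- summarize_costs(costs)
  atx_inpt <- s[s$cohort == "ATX" & s$component == "inpatient_cost", ]
  expect_identical(atx_inpt$median, 0)     # >50% zeros
  la <- s[s$cohort == "LA_MPH" & s$component == "prescription_cost", ]
  expect_identical(la$median, 5)
  atx_rx <- s[s$cohort == "ATX" & s$component == "prescription_cost", ]
  expect_identical(atx_rx$median, sort(c(10, 20, 30, 40))[2:3] |>
                     mean())               # sort-based oracle
})

test_that("cost tables round-trip through YAML", {
  tbl <- cost_table()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_cost_table(tbl, p)
  tbl2 <- read_cost_table(p)
  expect_equal(tbl2$drug_unit_costs, tbl$drug_unit_costs)
  expect_equal(tbl2$hicp_index, tbl$hicp_index)
  expect_identical(tbl2$reference_year, tbl$reference_year)
})
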