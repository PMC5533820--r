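# Independent brute-force oracles used across the suite. These deliberately
# materialize every follow-up day (or scan every candidate pair) and apply
# the classification rules literally, instead of reusing the package's
# interval arithmetic.

# --- day-grid treatment-pattern oracle --------------------------------------
# fills: data.frame(day, drug_class, supply_days); returns the same fields
# as evaluate_patient, computed on an explicit 0..364 day grid.
oracle_patterns <- function(fills, index_date, index_drug,
                            followup_days = 365L,
                            standard_gap = 30L, holiday_gap = 90L,
                            holiday_months = 5:7, switch_window = 30L,
                            switch_min_supply = 30L, aug_overlap = 30L) {
  last_day <- followup_days - 1L
  idx <- fills[fills$drug_class == index_drug & fills$day >= 0L, ,
               drop = FALSE]
  idx <- idx[order(idx$day), , drop = FALSE]
  non <- fills[fills$drug_class != index_drug & fills$day >= 0L, ,
               drop = FALSE]
  non <- non[non$drug_class %in%
               setdiff(c("ATX", "LA_MPH", "SA_MPH", "antipsychotic",
                         "tranquilizer", "antidepressant_mood",
                         "anticonvulsant", "hypnotic_sedative", "clonidine"),
                       index_drug), , drop = FALSE]
  non <- non[order(non$day, non$drug_class), , drop = FALSE]

  # stockpiling coverage, one day at a time
  covered <- rep(FALSE, followup_days)
  next_free <- 0L
  for (k in seq_len(nrow(idx))) {
    start <- max(idx$day[k], next_free)
    days <- seq(start, start + idx$supply_days[k] - 1L)
    covered[days[days <= last_day] + 1L] <- TRUE
    next_free <- start + idx$supply_days[k]
  }

  month_of <- function(d) as.integer(format(index_date + d, "%m"))

  # walk uncovered runs in day order
  disc_day <- NA_integer_; gap_start <- NA_integer_
  d <- 1L
  while (d <= last_day) {
    if (!covered[d + 1L]) {
      gs <- d
      ge <- gs
      while (ge < last_day && !covered[ge + 2L]) ge <- ge + 1L
      thr <- if (any(month_of(gs:(gs + standard_gap - 1L)) %in%
                     holiday_months)) holiday_gap else standard_gap
      if (ge - gs + 1L >= thr) {
        if (gs + thr <= last_day) {
          disc_day <- gs + thr
          gap_start <- gs
        }
        break
      }
      d <- ge + 1L
    } else d <- d + 1L
  }

  switch_day <- NA_integer_; switch_class <- NA_character_
  if (!is.na(disc_day)) {
    anchor <- gap_start - 1L
    for (k in seq_len(nrow(non))) {
      if (non$day[k] > anchor && non$day[k] <= anchor + switch_window &&
          non$day[k] <= last_day &&
          non$supply_days[k] >= switch_min_supply) {
        switch_day <- non$day[k]
        switch_class <- non$drug_class[k]
        break
      }
    }
  }

  aug_day <- NA_integer_; aug_class <- NA_character_
  for (k in seq_len(nrow(non))) {
    if (non$day[k] > last_day || non$day[k] < 0L) next
    span <- seq(non$day[k], min(non$day[k] + non$supply_days[k] - 1L,
                                last_day))
    if (sum(covered[span + 1L]) >= aug_overlap) {
      aug_day <- non$day[k]
      aug_class <- non$drug_class[k]
      break
    }
  }

  restart_day <- NA_integer_
  if (!is.na(disc_day)) {
    change <- if (!is.na(switch_day)) switch_day else disc_day
    cand <- idx$day[idx$day > change & idx$day <= last_day]
    if (length(cand)) restart_day <- min(cand)
  }

  persistence <- min(c(disc_day, switch_day, aug_day, followup_days),
                     na.rm = TRUE)
  first_change <- suppressWarnings(min(c(switch_day, aug_day),
                                       na.rm = TRUE))
  if (!is.finite(first_change)) first_change <- NA_integer_
  list(persistence_days = as.integer(persistence),
       discontinued = !is.na(disc_day), discontinuation_day = disc_day,
       switched = !is.na(switch_day), switch_day = switch_day,
       switch_to_class = switch_class,
       restarted = !is.na(restart_day), restart_day = restart_day,
       augmented = !is.na(aug_day), augment_day = aug_day,
       augment_class = aug_class,
       first_change_day = as.integer(first_change))
}

# random patient record set exercising gaps, stockpiling, holidays,
# switches and augmentations
random_patient_fills <- function() {
  index_date <- as.Date("2006-01-01") + sample.int(1800, 1)
  index_drug <- sample(c("ATX", "LA_MPH"), 1)
  n_idx <- sample(1:6, 1)
  idx_days <- c(0L, sort(sample(1:400, n_idx - 1L)))
  fills <- data.frame(day = idx_days, drug_class = index_drug,
                      supply_days = sample(5:90, n_idx, replace = TRUE),
                      stringsAsFactors = FALSE)
  n_non <- sample(0:4, 1)
  if (n_non > 0) {
    pool <- c("SA_MPH", "antipsychotic", "tranquilizer",
              "antidepressant_mood", "clonidine", "other",
              if (index_drug == "ATX") "LA_MPH" else "ATX")
    fills <- rbind(fills, data.frame(
      day = sample(0:400, n_non, replace = TRUE),
      drug_class = sample(pool, n_non, replace = TRUE),
      supply_days = sample(5:90, n_non, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  list(fills = fills, index_date = index_date, index_drug = index_drug)
}

run_engine_on <- function(case, rule = gap_rule()) {
  fills <- case$fills
  fills$date <- case$index_date + fills$day
  idx <- list(patient_id = "X", index_date = case$index_date,
              index_drug = case$index_drug)
  evaluate_patient(fills, idx, rule)
}

# --- naive greedy matcher ---------------------------------------------------
# same greedy semantics as greedy_match, written with explicit loops and
# explicit tie handling
oracle_greedy <- function(st, sc, caliper, order_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(order_seed)
  ord <- sample.int(length(st))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  used <- rep(FALSE, length(sc))
  pairs <- NULL
  for (i in ord) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_along(sc)) {
      if (used[j]) next
      d <- abs(sc[j] - st[i])
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (!is.na(best) && best_d <= caliper) {
      used[best] <- TRUE
      pairs <- rbind(pairs, data.frame(t = i, c = best))
    }
  }
  pairs
}

# --- eligibility re-check ---------------------------------------------------
# scans every selection rule independently for one patient
oracle_eligibility <- function(patient, fills, visits, cfg) {
  fills$date <- as.Date(fills$date)
  win <- fills$date >= cfg$selection_window[1] &
    fills$date <= cfg$selection_window[2]
  mono <- function(drug, other) {
    cand <- fills$date[win & fills$drug_class == drug]
    cand[!cand %in% fills$date[fills$drug_class == other]]
  }
  atx <- mono("ATX", "LA_MPH"); la <- mono("LA_MPH", "ATX")
  if (length(atx)) { d0 <- min(atx); drug <- "ATX" }
  else if (length(la)) { d0 <- min(la); drug <- "LA_MPH" }
  else return(list(indexed = FALSE))
  ok <- patient$age_at_index >= cfg$age_min &&
    patient$age_at_index <= cfg$age_max &&
    any(as.Date(visits$date) >= d0 - 365 & as.Date(visits$date) < d0) &&
    any(as.Date(visits$date) > d0 & as.Date(visits$date) <= d0 + 365) &&
    isTRUE(patient$adhd_dx_pre_index) &&
    !(any(fills$date >= d0 - 60 & fills$date <= d0 &
            fills$drug_class == "ATX") &&
        any(fills$date >= d0 - 60 & fills$date <= d0 &
              fills$drug_class == "LA_MPH")) &&
    !any(fills$date >= d0 - 60 & fills$date <= d0 &
           fills$drug_class == "SA_MPH") &&
    any(fills$date > d0 & fills$date <= d0 + 365 &
          fills$drug_class == drug)
  list(indexed = TRUE, index_drug = drug, index_date = d0, eligible = ok)
}

# --- Monte-Carlo replay of the generator's refill rules ---------------------
# returns the expected discontinuation rate among patients with >= 2 study
# drug fills, by simulating the generative chain and applying the gap rule
# literally (no engine code involved)
oracle_discontinuation_rate <- function(cfg, n_sim = 20000L) {
  win <- as.integer(cfg$selection_window[2] - cfg$selection_window[1])
  disc <- 0L; kept <- 0L
  for (s in seq_len(n_sim)) {
    idx <- cfg$selection_window[1] + sample.int(win + 1L, 1L) - 1L
    supply <- cfg$default_supply_days
    fill_days <- 0L
    repeat {
      exhausted <- fill_days[length(fill_days)] + supply
      if (exhausted > 420L) break
      if (stats::runif(1) < cfg$discontinue_prob) break
      gap <- max(0L, as.integer(round(stats::rlnorm(1,
                cfg$refill_gap_distribution$meanlog,
                cfg$refill_gap_distribution$sdlog))))
      m <- as.integer(format(idx + exhausted, "%m"))
      if (m %in% 4:7 && stats::runif(1) < cfg$holiday_gap_prob)
        gap <- sample(40:80, 1L)
      fill_days <- c(fill_days, exhausted + gap)
    }
    stopped <- fill_days[length(fill_days)] + supply <= 420L
    if (stopped && stats::runif(1) < cfg$switch_prob)
      stats::runif(1)  # switch class draw, irrelevant to index coverage
    if (stopped && stats::runif(1) < cfg$restart_prob)
      fill_days <- c(fill_days,
                     fill_days[length(fill_days)] + supply +
                       sample(40:120, 1L))
    if (length(fill_days) < 2L) next
    kept <- kept + 1L
    # literal gap scan on the index timeline
    o <- oracle_patterns(
      data.frame(day = fill_days, drug_class = "ATX",
                 supply_days = supply, stringsAsFactors = FALSE),
      idx, "ATX")
    if (o$discontinued) disc <- disc + 1L
  }
  c(rate = disc / kept, n = kept)
}
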