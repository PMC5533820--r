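---
title: "Classifying medication treatment patterns, matching cohorts and attributing costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying medication treatment patterns, matching cohorts and attributing costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxpatterns)
```

## The problem

Retrospective cohort studies of ADHD pharmacotherapy ask how children and
adolescents actually use their medication after starting it: how long they
persist on the index drug, whether they discontinue, switch to another
agent, restart, or augment with a second agent, and what resource use and
costs follow. The raw material is longitudinal EMR-style data: dated
prescription fills with days of supply, outpatient visits by specialty,
inpatient admissions and sick notes. `rxpatterns` implements the full
analytical chain for a two-cohort comparison of atomoxetine (ATX) against
long-acting methylphenidate (LA-MPH) monotherapy initiators:

1. **Cohort construction** (`build_cohorts`): index-date assignment with
   preferential ATX labelling, inclusion/exclusion rules, novel-initiator
   flagging.
2. **Propensity-score matching** (`fit_propensity`, `greedy_match`):
   1:1 greedy nearest-neighbour matching with a caliper, plus calibration
   and covariate-balance diagnostics.
3. **Treatment-pattern classification** (`evaluate_patient` and friends):
   the refill-gap engine at the heart of the package.
4. **Resource counting and costing** (`count_hru`, `apply_costs`).
5. **Comparison statistics** (`chi2_2x2`, `rank_sum_test`, `t_test`,
   `log_rank_test`, `glm_fit`).

A seeded synthetic generator (`generate_bundle`) and a deterministic
worked-example bundle (`make_table4_fixture`) supply data with the
structure the analysis assumes, since the EMR databases such analyses run
on are proprietary.

## The pattern-classification model

All classification happens on a 0-based day grid from the index date over
a 365-day follow-up (days 0–364). A patient's index-drug fills are first
turned into a **supply timeline** of disjoint covered intervals.

**Stockpiling.** By default an early refill starts contributing the day
after accumulated coverage ends, so supply is banked rather than wasted:
fills on days 0 and 30 of 60 days each cover days 0–119. With
`gap_rule(stockpile = FALSE)` each fill covers only its own window and the
overlap is lost (days 0–89 in the same example). Claims-analysis practice
uses both conventions; stockpiling is the default because the alternative
systematically understates possession for early refillers.

**Discontinuation.** A gap in coverage of at least 30 days
(`standard_gap_days`) ends the episode; the discontinuation date sits 30
days into the gap. Gaps beginning around the May–July school holidays are
tolerated up to 90 days (`holiday_gap_days`) to accommodate sanctioned
summer "drug holidays". The holiday threshold applies when *any of the
first 30 uncovered days* falls in May–July (`holiday_applies =
"first_standard_days"`); the stricter reading that only the gap's first
day counts is available as `"gap_start"`. We default to the broader
reading because a gap opening in late April that runs through the summer
is clinically the same pause as one opening May 1.

**Switching.** Assessed only among discontinuers: the earliest fill of a
non-index ADHD- or mental-health-indicated class (antipsychotics,
tranquilizers, antidepressants/mood stabilizers, anticonvulsants,
hypnotics/sedatives, clonidine) within 30 days of the end of coverage,
carrying at least 30 days of supply. Only the first switch is recorded.
The switch window is anchored at the *last covered day* rather than the
formal discontinuation date: the discontinuation date itself sits 30 days
into the gap, so anchoring there would let a "switch within 30 days of
discontinuation" begin up to 60 days after therapy actually lapsed. The
anchor is configurable (`switch_anchor = "discontinuation_date"`).

**Restarting.** The first index-drug fill after the switch date (for
switchers) or discontinuation date (for other discontinuers), before
follow-up ends.

**Augmentation.** The earliest non-index fill of an eligible class whose
own supply overlaps index coverage on at least 30 distinct days; only the
first augmentation is recorded, with its class.

**Persistence.** Days from index up to (not including) the earliest of
the discontinuation date, switch date and augmentation date, censored at
365. By default the tolerated 30 gap days before the discontinuation date
*count* toward persistence, matching a definition that runs "until
discontinuation" with the discontinuation date 30 days into the gap;
`gap_rule(persistence_includes_gap = FALSE)` stops persistence at the end
of supplied coverage instead. Same-day ties resolve in the order
discontinuation < switch < augmentation. The day of the first switch or
augmentation is binned 0–90 / 91–180 / 181–360 days, closed on both ends.

**A non-obvious interaction.** Persistence is *not* monotone in the fill
set under the full rule: removing a fill makes coverage end earlier, and
a gap that starts earlier can slide into May–July, flip to the 90-day
threshold and stop counting as a discontinuation; shrinking coverage can
likewise dissolve an augmentation overlap, moving the episode end from
the augmentation date to a later discontinuation date. Under a single gap
threshold and considering index fills only, monotonicity holds (gap ends
are pinned to actual fill dates, so removing fills only lengthens gaps or
moves them earlier), and the test suite verifies exactly that property.

## Cohort construction

The index date is the first qualifying monotherapy fill (no fill of the
other study drug the same day) inside the 2006–2010 selection window.
Patients with any qualifying ATX candidate are indexed on ATX even when
an LA-MPH candidate comes first (preferential assignment, maximizing the
smaller cohort); ties on the same day also resolve to ATX. Exclusions, in
rule order: age outside 6–17 at index; no recorded visit in the 365-day
baseline or the 365-day follow-up, or no pre-index ADHD diagnosis
("available data" is not further defined in the source setting, so we
operationalize it this way, configurably); receipt of both study drugs at
index or within the prior 60 days; any short-acting methylphenidate
(SA-MPH) in the same window; no *second* index-drug fill during
follow-up — the index fill itself does not count, so included patients
have at least two fills. Baseline is half-open `[index − 365, index)`,
follow-up `(index, index + 365]`. Novel initiators have no ADHD-indicated
fill in the baseline window. Diagnoses are pre-coded flags
(`adhd_dx_pre_index`) on the patient table; no ICD-10 parsing is
attempted.

## Matching and diagnostics

The propensity model is a maximum-likelihood logistic regression of ATX
receipt on age group (6–12/13–17), sex, index year, region, practice
specialty, baseline comorbidity flags, baseline other-medication use,
ADHD-medication naïvety and baseline visit/admission counts, fitted by
IRLS (tolerance 1e-8, 100 iterations). Complete separation is detected
(degenerate fitted probabilities or exploding coefficients) and handled
by a small ridge penalty (1e-4) on the non-intercept terms, with the
result flagged — a deliberate, documented fallback rather than silent
divergence.

Matching is greedy 1:1 nearest-neighbour without replacement under a
caliper of 0.0001. The caliper is interpreted on the probability scale by
default (the source setting states the bare number without a scale);
`psm$scale = "logit"` switches it. Greedy results depend on processing
order, which is unstated in the field's descriptions, so treated units
are visited in a seed-shuffled order (`order_seed`), making the match
reproducible and the order an explicit analysis input. Nearest-neighbour
ties break toward the control appearing first in the input, for
determinism.

Two diagnostics are reported. Model calibration is checked with the
Hosmer–Lemeshow decile test *on the fitting sample*. Match quality is
checked with `decile_balance()`: cohort membership cross-tabulated
against pooled score deciles in the matched sample. A goodness-of-fit
test of observed treatment against fitted scores *within the matched
sample* would reject by construction — a 1:1 matched sample has 50%
treated prevalence at every score level — so that variant is not used.
`balance_report()` adds standardized mean differences per covariate
before and after matching, flagging |SMD| > 0.1.

## Resource use and costs

Counts over `(index, index + 365]`: prescriptions by drug class and
grouped as index drug / other ADHD-indicated / other mental-health /
other; outpatient visits by specialty; admissions; sick notes. Costs come
from a configurable tariff table: euros per prescription by class;
fee-schedule points per visit by specialty at €0.035 per point; a
weighted-average admission cost; and a consumer-price index series that
inflates each component from its tariff year (drugs and visits 2011,
admissions 2012, configurable) to 2012 euros. The shipped tariff values
are **illustrative placeholders** — real German tariff catalogues (drug
price list, outpatient fee scale, DRG catalogue) are licensed data — so
absolute cost levels from the defaults mean nothing; comparisons and
pipeline mechanics are what the defaults support, and every summary
carries the tariff configuration used. Because it is ambiguous which
prescriptions belong in "ADHD-related" costs, both aggregates are
reported: `prescription_cost` (ADHD-indicated plus mental-health classes,
used in the headline `total_cost`) and `prescription_cost_all`.

## Inference

Categorical comparisons use the uncorrected Pearson chi-squared — the
uncorrected form is what reproduces the printed reference p-values
(0.045, 0.003, 0.635) from their contingency counts; the Yates-corrected
version does not (0.060 for the first). Continuous comparisons use the
Wilcoxon rank-sum test (exact enumeration for ≤ 20 observations per arm
without ties, normal approximation with tie correction otherwise) or the
Welch t test. Persistence is compared with the log-rank test, taking
episode termination by discontinuation/switch/augmentation as the event
and censoring at day 365 (the censoring scheme is our choice; the source
setting does not state one). Residual-difference checks use log-link
GLMs: negative binomial for counts (dispersion profiled by maximum
likelihood via `MASS::glm.nb`) and gamma for positive costs. All tests
are two-sided at α = 0.05 with no multiplicity adjustment.

## The synthetic generator

`generate_bundle()` emulates the *structure* of a German office-based EMR
panel: patients aged 6–17 (about 80% male, 2006–2010 index dates inside a
2005–2011 data span), a drug mix of ATX/LA-MPH/SA-MPH first fills,
60-day default supply, and a refill chain in which each supply exhaustion
ends therapy with probability 0.12 or resumes after a lognormal
(meanlog log 7, sdlog 0.8) gap in days; gaps opening near the summer
months are stretched to 40–80 days with probability 0.25. Discontinuers
may switch (0.15) and/or restart after 40–120 days (0.55); augmentation
adds a concurrent non-index fill (0.15). A configurable fraction carries
baseline ADHD fills (ongoing users, 0.34) or an SA-MPH fill near index
(0.05), so cohort construction produces realistic attrition. Visits are
Poisson (8/year) around the patient's practice specialty; admissions are
rare (0.1/year). None of these micro-parameters is reported for the real
database — they are stated choices, made once as plausible for paediatric
ADHD pharmacotherapy, not estimates. The generator reproduces itself
byte-for-byte under a fixed seed and never touches the caller's RNG
state.

What passing tests on synthetic data do **not** show: the generator makes
no attempt at the real covariate joint distribution, regional prevalence,
physician sampling weights, dose titration or informative loss to
follow-up, so absolute rates, costs and between-cohort contrasts from
synthetic runs say nothing about the real population — they validate the
machinery, not the epidemiology.

`make_table4_fixture()` is different: a fully deterministic bundle of 974
novel initiators whose timelines are constructed *backwards* from target
event labels (a switcher gets a qualifying fill just after coverage ends,
an augmenter a 30-day overlapping fill, and so on), so that running the
actual engine over it reproduces a known results table exactly — 43 vs 27
switchers, 87/126 (69.0%) vs 171/181 (94.5%) restarters, 83 vs 89
augmenters, 80/26/20 vs 75/29/12 first-change strata. All fixture
patients index on 2008-08-01 with engineered gaps starting by day 243, so
the first 30 days of every gap precede May and the standard 30-day rule
applies throughout; the fixture therefore exercises the engine's plain
path while the random property tests cover the holiday logic. Because
correctness of the fixture is certified by the engine itself, the
acceptance checks on it are genuine end-to-end computations, not lookups.

## Numerical and degenerate-input choices

- Dates are calendar `Date`s; all engine arithmetic is integer day
  offsets. Ages are stored as completed years at index (no birthdates).
- Percentages over an empty denominator are `NA`, never 0; a
  majority-zero cost component has median 0 by order statistics.
- Zero-margin 2×2 tables, single-class treatment, empty samples and
  zero-variance t-test inputs raise errors (or p = 1 where the answer is
  exact); degenerate Hosmer–Lemeshow groups are merged and counted.
- Empty treated or control sets yield an empty match with a warning.
- A zero-patient study configuration exits cleanly with empty reports.

## Problem sizes in the test suite

The suite checks the engine against a literal day-grid oracle on 1000
random timelines; greedy matching against a naive scan oracle on 100×100
instances; type-I error of the chi-squared, t and log-rank tests at 2000
null simulations each (accepting 3.5–6.5% rejection at nominal 5%);
logistic recovery at n = 5000 and NB/gamma recovery at n = 2000 within 3
standard errors; and the generator's discontinuation rate against a
20,000-replicate Monte-Carlo replay of its own generative rules. These
sizes give stable verdicts for the properties tested while keeping the
default run fast.

## Known limitations

- Only the first switch and first augmentation are modelled; no
  multi-switch sequences, dose or titration modelling.
- Monotherapy at index is operationalized as "no fill of the other study
  drug on the candidate date" plus the 60-day look-back; a patient of one
  cohort who later fills the other study drug inside the selection window
  is re-evaluated under preferential assignment, which can re-index them.
- The cost table is illustrative; no non-pharmacological intervention
  costs.
- Matching supports greedy 1:1 with caliper only — no optimal or full
  matching, no replacement, no weighting.
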