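#' Drug class vocabulary
#'
#' Closed set of drug-class labels used throughout the package. The three
#' ADHD pharmacotherapy classes are atomoxetine (`ATX`), long-acting
#' methylphenidate (`LA_MPH`) and short-acting methylphenidate (`SA_MPH`);
#' the remaining mental-health classes are eligible targets for switching
#' and augmentation; `other` captures all unrelated medication.
#'
#' @return Character vector of class labels.
#' @export
drug_classes <- function() {
  c("ATX", "LA_MPH", "SA_MPH",
    "antipsychotic", "tranquilizer", "antidepressant_mood",
    "anticonvulsant", "hypnotic_sedative", "clonidine", "other")
}

#' @rdname drug_classes
#' @export
adhd_classes <- function() c("ATX", "LA_MPH", "SA_MPH")

#' @rdname drug_classes
#' @export
mental_health_classes <- function() {
  c("antipsychotic", "tranquilizer", "antidepressant_mood",
    "anticonvulsant", "hypnotic_sedative", "clonidine")
}

# classes a patient can switch to / augment with: any non-index ADHD class
# or a mental-health class ("other" medication never qualifies)
change_classes <- function(index_drug) {
  setdiff(c(adhd_classes(), mental_health_classes()), index_drug)
}

regions <- function() paste0("R", 1:8)

insurance_levels <- function() c("member", "dependant", "private", "retiree")

specialties <- function() {
  c("general_internal", "paediatrics", "psychiatry", "neurology")
}

comorbidity_labels <- function() {
  c("learning_difficulties", "accidental_injury", "anxiety",
    "conduct_disorder", "emotional_disorder")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so package functions never disturb the
# global random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 32-bit seed from a global seed, deterministically.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset) * 1009L) %% 2147483647L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
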