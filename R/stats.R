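#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-squared test with
#' expected counts from the margins and 1 degree of freedom. The table is
#' laid out rows = cohorts, columns = event yes/no.
#'
#' @param a,b,c,d Non-negative integer cell counts: `(a, b)` first row,
#'   `(c, d)` second row.
#' @return A `test_result` list: `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chi2_2x2(43, 443, 27, 461)$p_value   # ~0.045
#' @export
chi2_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0) || sum(m) == 0) stop("counts must be non-negative, n > 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a margin is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result(unname(ht$statistic), 1L, unname(ht$p.value),
              "Pearson chi-squared (uncorrected)")
}

# r x c Pearson chi-squared (uncorrected); used for multi-level rows such
# as time-to-first-change strata
chi2_rxc <- function(m) {
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result(unname(ht$statistic), unname(ht$parameter),
              unname(ht$p.value), "Pearson chi-squared (uncorrected)")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum comparison with mid-ranks for ties: exact
#' enumeration when both samples have at most 20 observations and no ties
#' are present, otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A `test_result` list.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(test_result(0, 1L, 1, "Wilcoxon rank-sum"))
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  test_result(unname(ht$statistic), 1L, unname(ht$p.value),
              if (exact) "Wilcoxon rank-sum (exact)"
              else "Wilcoxon rank-sum (normal approximation)")
}

#' Two-sample t test
#'
#' Two-sided two-sample t test, Welch by default (`pooled = TRUE` gives
#' the equal-variance version). Samples that are both constant return
#' p = 1 when the means agree and an error otherwise.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param pooled Use the pooled-variance statistic.
#' @return A `test_result` list.
#' @export
t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, length(x) + length(y) - 2L, 1, "t test"))
    stop("degenerate variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  test_result(unname(ht$statistic), unname(ht$parameter),
              unname(ht$p.value),
              if (pooled) "t test (pooled)" else "Welch t test")
}

#' Log-rank test for two groups
#'
#' Standard log-rank chi-squared comparison of time-to-event experience
#' between two groups, one degree of freedom, censoring allowed. In the
#' persistence analysis, time is persistence days, an event is an episode
#' terminated by discontinuation, switch or augmentation, and follow-up
#' survivors are censored at the end of follow-up.
#'
#' @param time Positive event/censoring times.
#' @param event Logical (or 0/1) event indicator.
#' @param group Two-level group labels.
#' @return A `test_result` list.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups required")
  ev <- as.integer(event)
  if (any(tapply(ev, group, sum) == 0))
    warning("a group has no events; it contributes zero observed events")
  sd <- survival::survdiff(survival::Surv(time, ev) ~ group)
  test_result(unname(sd$chisq), 1L,
              stats::pchisq(sd$chisq, 1L, lower.tail = FALSE), "log-rank")
}

#' Generalized linear model fit for utilization and cost outcomes
#'
#' Log-link maximum-likelihood fits used as residual-difference checks:
#' negative binomial for count outcomes (dispersion profiled via maximum
#' likelihood) and gamma for strictly positive cost outcomes. Returns the
#' coefficient table with Wald standard errors and p-values;
#' non-convergence is flagged rather than silent.
#'
#' @param outcome Counts (negative binomial) or positive reals (gamma).
#' @param covariates Data frame of predictors.
#' @param family `"negative_binomial"` or `"gamma"`.
#' @return A list with `coefficients` (term/estimate/std_error/p_value),
#'   `family`, `converged` and `dispersion` (NB theta or gamma shape).
#' @export
glm_fit <- function(outcome, covariates,
                    family = c("negative_binomial", "gamma")) {
  family <- match.arg(family)
  df <- data.frame(.y = outcome, covariates)
  if (family == "negative_binomial") {
    if (any(outcome < 0) || any(outcome != round(outcome)))
      stop("negative binomial outcomes must be non-negative integers")
    fit <- suppressWarnings(MASS::glm.nb(.y ~ ., data = df,
                                         control = stats::glm.control(
                                           maxit = 200L)))
    dispersion <- fit$theta
  } else {
    if (any(outcome <= 0))
      stop("gamma outcomes must be strictly positive")
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::Gamma(link = "log"),
                                       control = stats::glm.control(
                                         maxit = 200L)))
    dispersion <- 1 / summary(fit)$dispersion
  }
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1], std_error = sm[, 2],
                                 p_value = sm[, 4],
                                 stringsAsFactors = FALSE,
                                 row.names = NULL),
       family = family, converged = fit$converged,
       dispersion = dispersion)
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = as.numeric(statistic), df = df,
                 p_value = as.numeric(p_value), method = method,
                 two_sided = TRUE, alpha = 0.05),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, format(x$df), x$p_value))
  invisible(x)
}
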