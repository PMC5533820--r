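#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment receipt on the
#' supplied covariates, fitted by iteratively reweighted least squares
#' (convergence when the relative deviance change drops below `1e-8`, at
#' most 100 iterations). When the fit shows signs of complete separation
#' (fitted probabilities numerically at 0 or 1, or exploding
#' coefficients), the model is refitted with a small ridge penalty on the
#' non-intercept coefficients and the result flagged.
#'
#' @param covariates Data frame of covariates (factors are one-hot encoded
#'   against their first level via the usual model-matrix contrasts); no
#'   missing values.
#' @param treatment Binary vector (0/1 or logical), both classes present.
#' @param ridge Penalty used by the separation fallback.
#' @return An object of class `propensity_model`: coefficient table with
#'   Wald standard errors, fitted scores, convergence information and a
#'   `separation` flag.
#' @export
fit_propensity <- function(covariates, treatment, ridge = 1e-4) {
  y <- as.numeric(treatment)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("treatment must be binary with no missing values")
  if (length(unique(y)) < 2L)
    stop("both treatment classes must be present")
  if (anyNA(covariates)) stop("covariates must not contain missing values")
  X <- stats::model.matrix(~ ., data = covariates)

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p < 1e-10 | p > 1 - 1e-10) ||
    any(abs(fit$coefficients) > 15, na.rm = TRUE)
  if (separated) {
    warning("possible separation in propensity model; ",
            "refitting with a small ridge penalty")
    rf <- ridge_logistic(X, y, lambda = ridge)
    coefs <- rf$coefficients
    p <- rf$fitted
    se <- rf$se
    iter <- rf$iter
    deviance <- rf$deviance
  } else {
    coefs <- fit$coefficients
    # Wald standard errors from the final IRLS weights
    W <- p * (1 - p)
    XtWX <- crossprod(X * sqrt(W))
    se <- sqrt(diag(solve(XtWX)))
    iter <- fit$iter
    deviance <- fit$deviance
  }
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(coefs),
                              std_error = unname(se),
                              stringsAsFactors = FALSE),
    fitted = as.numeric(p),
    covariate_spec = colnames(X),
    convergence = list(iterations = iter, deviance = deviance),
    separation = separated), class = "propensity_model")
}

# ridge-penalised logistic IRLS (penalty off the intercept); used only as
# the separation fallback of fit_propensity
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 200L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / W
    H <- crossprod(X * sqrt(W)) + pen
    beta <- drop(solve(H, crossprod(X, W * z)))
    dev <- -2 * sum(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  p <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * sqrt(pmax(p * (1 - p), 1e-10))) + pen
  list(coefficients = stats::setNames(beta, colnames(X)), fitted = p,
       se = sqrt(diag(solve(H))), iter = it, deviance = dev)
}

#' Greedy 1:1 nearest-neighbour caliper matching
#'
#' Treated units are visited in a seed-shuffled random order; each takes
#' the nearest not-yet-matched control by absolute score difference,
#' without replacement, and the pair is kept only when the difference is
#' within the caliper. Nearest-neighbour ties are broken in favour of the
#' control appearing first in the input. The result is fully determined by
#' the inputs and `order_seed`.
#'
#' @param scores_treated,scores_control Numeric propensity scores; names
#'   (or positions, when unnamed) identify the units.
#' @param caliper Maximum allowed absolute score difference (> 0).
#' @param order_seed Seed for the processing order of treated units.
#' @return An object of class `match_set`: data frame `pairs`
#'   (`treated_id`, `control_id`, `score_treated`, `score_control`),
#'   unmatched id vectors, the caliper and the seed.
#' @export
greedy_match <- function(scores_treated, scores_control, caliper = 1e-4,
                         order_seed = 1L) {
  if (caliper <= 0) stop("caliper must be positive")
  tid <- names(scores_treated) %||% as.character(seq_along(scores_treated))
  cid <- names(scores_control) %||% as.character(seq_along(scores_control))
  empty <- data.frame(treated_id = character(), control_id = character(),
                      score_treated = numeric(), score_control = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(scores_treated) || !length(scores_control)) {
    warning("empty treated or control set; nothing to match")
    return(structure(list(pairs = empty, unmatched_treated = tid,
                          unmatched_control = cid, caliper = caliper,
                          order_seed = order_seed), class = "match_set"))
  }
  ord <- with_seed(order_seed, sample.int(length(scores_treated)))
  avail <- rep(TRUE, length(scores_control))
  sc <- as.numeric(scores_control)
  st <- as.numeric(scores_treated)
  m_t <- integer(0); m_c <- integer(0)
  for (i in ord) {
    d <- abs(sc - st[i])
    d[!avail] <- Inf
    j <- which.min(d)          # ties -> earliest control in input order
    if (is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      m_t <- c(m_t, i); m_c <- c(m_c, j)
    }
  }
  pairs <- if (length(m_t))
    data.frame(treated_id = tid[m_t], control_id = cid[m_c],
               score_treated = st[m_t], score_control = sc[m_c],
               stringsAsFactors = FALSE) else empty
  structure(list(pairs = pairs,
                 unmatched_treated = setdiff(tid, pairs$treated_id),
                 unmatched_control = setdiff(cid, pairs$control_id),
                 caliper = caliper, order_seed = order_seed),
            class = "match_set")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Cuts the fitted scores into `n_groups` equal-count groups and compares
#' observed with expected event counts: the statistic is
#' `sum((O - E)^2 / (E * (1 - E/n)))` over groups, referred to a
#' chi-squared distribution with `n_groups - 2` degrees of freedom.
#' Degenerate groups (expected count 0 or equal to the group size) are
#' merged with their neighbour and the merge reported.
#'
#' @param scores Fitted probabilities.
#' @param outcomes Binary outcomes.
#' @param n_groups Number of calibration groups (default 10, deciles).
#' @return A list with `statistic`, `df`, `p_value`, the per-group table
#'   and the number of merges applied.
#' @export
hosmer_lemeshow <- function(scores, outcomes, n_groups = 10L) {
  if (n_groups < 2L) stop("n_groups must be at least 2")
  y <- as.numeric(outcomes)
  br <- unique(stats::quantile(scores, probs = seq(0, 1,
                                                   length.out = n_groups + 1L),
                               type = 2))
  g <- cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(n = as.integer(tapply(y, g, length)),
                    observed = as.numeric(tapply(y, g, sum)),
                    expected = as.numeric(tapply(scores, g, sum)))
  merges <- 0L
  repeat {
    bad <- which(tab$expected <= 1e-12 |
                   tab$expected >= tab$n - 1e-12)
    if (!length(bad) || nrow(tab) <= 2L) break
    k <- bad[1]
    into <- if (k == 1L) 2L else k - 1L
    tab[into, ] <- tab[into, ] + tab[k, ]
    tab <- tab[-k, , drop = FALSE]
    merges <- merges + 1L
  }
  term <- (tab$observed - tab$expected)^2 /
    (tab$expected * (1 - tab$expected / tab$n))
  statistic <- sum(term)
  df <- max(nrow(tab) - 2L, 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       groups = tab, merged = merges)
}

#' Decile balance of propensity scores in a matched sample
#'
#' Cuts the pooled matched-sample scores into `n_groups` equal-count
#' groups and tests, with an uncorrected Pearson chi-squared, whether
#' treated and control units are distributed alike across them. In a
#' well-matched 1:1 sample the two cohorts should be balanced within every
#' score decile. (This is the matched-sample analogue of a calibration
#' check: a goodness-of-fit test of observed treatment against the fitted
#' scores would reject by construction in a 1:1 matched sample, whose
#' treated prevalence is 50% regardless of the score level.)
#'
#' @param scores Propensity scores of the matched units.
#' @param treatment Binary treatment of the matched units.
#' @param n_groups Number of score groups (default deciles).
#' @return A `test_result` list.
#' @export
decile_balance <- function(scores, treatment, n_groups = 10L) {
  br <- unique(stats::quantile(scores, probs = seq(0, 1,
                                                   length.out = n_groups + 1L),
                               type = 2))
  g <- cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(g, as.integer(treatment))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  chi2_rxc(tab)
}

#' Covariate balance report (standardized mean differences)
#'
#' For every column of the covariate matrix, the standardized mean
#' difference between treated and control, before matching and within the
#' matched sample; the pooled standard deviation `sqrt((s1^2 + s2^2)/2)`
#' of the compared samples is the denominator. Post-match values with
#' `|SMD| > 0.1` are flagged. A covariate with zero pooled variance gets
#' SMD 0 when the means agree and `NA` (flagged degenerate) otherwise.
#'
#' @param covariates Numeric data frame or matrix, one row per unit, row
#'   names identifying units.
#' @param treatment Binary vector aligned with `covariates`.
#' @param match A [greedy_match()] result.
#' @return Data frame with `covariate`, `smd_pre`, `smd_post`,
#'   `flag_post` and `degenerate`.
#' @export
balance_report <- function(covariates, treatment, match) {
  X <- as.matrix(covariates)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  y <- as.numeric(treatment)
  smd <- function(a, b) {
    v <- function(x) if (length(x) > 1L) stats::var(x) else 0
    sp <- sqrt((v(a) + v(b)) / 2)
    if (!is.finite(sp) || sp < 1e-12) {
      if (abs(mean(a) - mean(b)) < 1e-12) return(c(0, TRUE))
      return(c(NA_real_, TRUE))
    }
    c((mean(a) - mean(b)) / sp, FALSE)
  }
  pre_t <- X[y == 1, , drop = FALSE]
  pre_c <- X[y == 0, , drop = FALSE]
  post_t <- X[match$pairs$treated_id, , drop = FALSE]
  post_c <- X[match$pairs$control_id, , drop = FALSE]
  out <- do.call(rbind, lapply(colnames(X), function(v) {
    pre <- smd(pre_t[, v], pre_c[, v])
    post <- if (nrow(post_t)) smd(post_t[, v], post_c[, v]) else c(NA, FALSE)
    data.frame(covariate = v, smd_pre = pre[1], smd_post = post[1],
               flag_post = is.finite(post[1]) && abs(post[1]) > 0.1,
               degenerate = pre[2] > 0 | post[2] > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Encode the baseline covariate table for the propensity model
#'
#' Assembles, for the eligible patients, the covariates entering the
#' propensity model: age group (6-12 vs 13-17), sex, index year,
#' geographical region, practice specialty, baseline comorbidity flags,
#' baseline other-medication use, ADHD-medication-naivety (the novel
#' initiator flag) and baseline outpatient-visit and inpatient-admission
#' counts.
#'
#' @param bundle An EMR bundle.
#' @param cohorts Output of [build_cohorts()] (eligible rows are used).
#' @param cfg A [selection_config()].
#' @return Data frame with row names = patient ids; factor and numeric
#'   columns ready for [fit_propensity()].
#' @export
encode_covariates <- function(bundle, cohorts, cfg = selection_config()) {
  el <- cohorts[cohorts$eligible, , drop = FALSE]
  p <- bundle$patients[match(el$patient_id, bundle$patients$patient_id), ]
  d0 <- as.Date(el$index_date)

  count_window <- function(tab, id, from, to) {
    if (!nrow(tab)) return(rep(0L, length(id)))
    key <- paste(tab$patient_id)
    vapply(seq_along(id), function(i) {
      d <- as.Date(tab$date[key == id[i]])
      sum(d >= from[i] & d < to[i])
    }, integer(1))
  }
  base_visits <- count_window(bundle$visits, el$patient_id,
                              d0 - cfg$baseline_days, d0)
  base_adm <- count_window(bundle$admissions, el$patient_id,
                           d0 - cfg$baseline_days, d0)
  rx <- bundle$prescriptions
  base_other_med <- vapply(seq_along(el$patient_id), function(i) {
    d <- rx[rx$patient_id == el$patient_id[i], ]
    any(as.Date(d$date) >= d0[i] - cfg$baseline_days &
          as.Date(d$date) < d0[i] &
          d$drug_class %in% c(mental_health_classes(), "other"))
  }, logical(1))

  com <- strsplit(p$comorbidity_flags, ";", fixed = TRUE)
  com_cols <- lapply(comorbidity_labels(), function(lab)
    vapply(com, function(x) lab %in% x, logical(1)))
  names(com_cols) <- paste0("com_", comorbidity_labels())

  out <- data.frame(
    age_group = factor(ifelse(p$age_at_index <= 12L, "6-12", "13-17"),
                       levels = c("6-12", "13-17")),
    sex = factor(p$sex, levels = c("male", "female")),
    index_year = factor(format(d0, "%Y")),
    region = factor(p$region, levels = regions()),
    specialty = factor(p$practice_specialty, levels = specialties()),
    adhd_naive = el$novel_initiator,
    baseline_other_med = base_other_med,
    baseline_visits = base_visits,
    baseline_admissions = base_adm,
    com_cols,
    stringsAsFactors = FALSE)
  rownames(out) <- el$patient_id
  # drop constant factors/columns (a single index year, say) so the model
  # matrix stays full rank
  keep <- vapply(out, function(col) length(unique(col)) > 1L, logical(1))
  out[, keep, drop = FALSE]
}
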