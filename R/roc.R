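# Empirical ROC machinery with DeLong placement values.
#
# Placement value of a case x against the controls: the fraction of
# controls it beats, counting ties half. The AUC is the mean case
# placement; DeLong's variance estimator is built from the empirical
# variances of the case and control placements.

# Placements of each element of x within the sorted vector sy (length n):
# (#(sy < x) + 0.5 * #(sy == x)) / n. O((m + n) log n).
placements <- function(x, sy) {
  n <- length(sy)
  n_le <- findInterval(x, sy)
  n_lt <- findInterval(x, sy, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / n
}

#' Empirical (Mann-Whitney) AUC with DeLong variance
#'
#' Computes the tie-corrected empirical AUC
#' \deqn{\hat{A} = \frac{\#(x > y) + 0.5\,\#(x = y)}{mn}}
#' over all case-control pairs, together with DeLong's variance estimator
#' \eqn{S_{10}/m + S_{01}/n} (the variances of case and control placement
#' values) and a normal-approximation confidence interval truncated to
#' [0, 1]. Higher scores are taken to indicate cases; no automatic
#' direction flipping is performed.
#'
#' @param case_scores scores of patients with the outcome (cases).
#' @param control_scores scores of patients without the outcome (controls).
#' @param conf.level confidence level for the CI, default 0.95.
#' @return object of class `roc_auc`: `auc`, `variance`, `ci_low`,
#'   `ci_high`, and the placement vectors `v10` (cases) and `v01`
#'   (controls).
#' @examples
#' coh <- study_cohort()
#' empirical_auc(coh$gbs[coh$hrel], coh$gbs[!coh$hrel])  # AUC 0.639
#' @export
empirical_auc <- function(case_scores, control_scores, conf.level = 0.95) {
  m <- length(case_scores)
  n <- length(control_scores)
  if (m == 0L || n == 0L) {
    stop("both case and control groups must be non-empty", call. = FALSE)
  }
  v10 <- placements(case_scores, sort(control_scores))
  v01 <- 1 - placements(control_scores, sort(case_scores))
  auc <- mean(v10)
  variance <- if (m > 1L && n > 1L) {
    stats::var(v10) / m + stats::var(v01) / n
  } else NA_real_
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- if (is.na(variance)) c(NA_real_, NA_real_) else {
    pmin(pmax(auc + c(-1, 1) * z * sqrt(variance), 0), 1)
  }
  structure(list(auc = auc, variance = variance,
                 ci_low = ci[1], ci_high = ci[2],
                 v10 = v10, v01 = v01,
                 n_case = m, n_control = n, conf.level = conf.level),
            class = "roc_auc")
}

#' @export
print.roc_auc <- function(x, digits = 3, ...) {
  cat(sprintf("Empirical AUC %.*f (%d cases, %d controls)\n",
              digits, x$auc, x$n_case, x$n_control))
  if (!is.na(x$variance)) {
    cat(sprintf("  DeLong SE %.*f; %g%% CI %.*f-%.*f\n", digits,
                sqrt(x$variance), 100 * x$conf.level,
                digits, x$ci_low, digits, x$ci_high))
  }
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same patients against
#' the same outcome, using DeLong's covariance of the paired placement
#' values:
#' \deqn{z = \frac{\hat A_b - \hat A_a}
#'   {\sqrt{\mathrm{var}(\hat A_a) + \mathrm{var}(\hat A_b)
#'    - 2\,\mathrm{cov}(\hat A_a, \hat A_b)}}}
#' with a two-sided p-value from the standard normal. Identical scores
#' (zero variance of the difference) give `z = 0`, `p = 1` by convention.
#'
#' @param scores_a,scores_b per-patient scores under the two models, in the
#'   same patient order.
#' @param outcome logical outcome per patient (`TRUE` = case).
#' @return object of class `delong_test`: `auc_a`, `auc_b`, `difference`,
#'   `variance` (of the difference), `z`, `p.value`, and the two `roc_auc`
#'   objects.
#' @examples
#' coh <- study_cohort()
#' delong_paired_test(coh$gbs, combined_score(coh$gbs, coh$nga), coh$hrel)
#' @export
delong_paired_test <- function(scores_a, scores_b, outcome) {
  stopifnot(length(scores_a) == length(outcome),
            length(scores_b) == length(outcome))
  outcome <- as.logical(outcome)
  ra <- empirical_auc(scores_a[outcome], scores_a[!outcome])
  rb <- empirical_auc(scores_b[outcome], scores_b[!outcome])
  m <- ra$n_case
  n <- ra$n_control
  s10 <- stats::cov(cbind(ra$v10, rb$v10))
  s01 <- stats::cov(cbind(ra$v01, rb$v01))
  s <- s10 / m + s01 / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  diff <- rb$auc - ra$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ra$auc, auc_b = rb$auc, difference = diff,
                 variance = var_diff, z = z, p.value = p,
                 roc_a = ra, roc_b = rb),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, digits = 3, ...) {
  cat(sprintf("Paired DeLong test: AUC %.*f vs %.*f (difference %.*f)\n",
              digits, x$auc_a, digits, x$auc_b, digits, x$difference))
  cat(sprintf("  z = %.3f, two-sided p = %s\n", x$z,
              format.pval(x$p.value, digits = 3, eps = 1e-16)))
  invisible(x)
}

#' ROC curve points
#'
#' Empirical (false positive rate, true positive rate) pairs of the rule
#' "positive iff score > cutoff", one row per cutoff from one below the
#' minimum score to the maximum.
#'
#' @param score per-patient score.
#' @param outcome logical outcome per patient.
#' @return data frame with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(score, outcome) {
  outcome <- as.logical(outcome)
  cuts <- c(min(score) - 1, sort(unique(score)))
  do.call(rbind, lapply(cuts, function(k) {
    data.frame(cutoff = k,
               fpr = mean(score[!outcome] > k),
               tpr = mean(score[outcome] > k))
  }))
}
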