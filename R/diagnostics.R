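#' Confusion counts for a binary rule
#'
#' Crosses a binary high-risk prediction against the lesion outcome.
#' The positive condition is an observed high-risk endoscopic lesion; the
#' positive test is a prediction of high risk.
#'
#' @param records cohort data frame with `hrel`.
#' @param rule either a logical vector (one prediction per record, `TRUE` =
#'   predicted high-risk) or a function taking `records` and returning one.
#' @return object of class `two_by_two` with fields `tp`, `fp`, `fn`, `tn`.
#' @examples
#' coh <- study_cohort()
#' two_by_two(coh, nga_is_bloody(coh$nga))  # 24 / 11 / 11 / 69
#' @export
two_by_two <- function(records, rule) {
  positive <- if (is.function(rule)) rule(records) else rule
  if (!is.logical(positive) || length(positive) != nrow(records)) {
    stop("'rule' must yield one logical prediction per record",
         call. = FALSE)
  }
  hrel <- records$hrel
  structure(list(tp = sum(positive & hrel), fp = sum(positive & !hrel),
                 fn = sum(!positive & hrel), tn = sum(!positive & !hrel)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(test = c("positive", "negative"),
                              lesion = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf.level confidence level, default 0.95.
#' @return `c(lower, upper)` on the proportion scale; the lower bound is 0
#'   when `x == 0` and the upper bound 1 when `x == n`.
#' @export
clopper_pearson <- function(x, n, conf.level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, x >= 0, x <= n, n > 0)
  alpha <- 1 - conf.level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive values of a
#' 2x2 table, each with a Clopper-Pearson 95% CI, all on the percentage
#' scale. A metric whose denominator is zero is reported as `NA`.
#'
#' @param tbl a [two_by_two()] object.
#' @param conf.level confidence level, default 0.95.
#' @return data frame with columns `metric`, `estimate`, `ci_low`,
#'   `ci_high` (percent).
#' @examples
#' diagnostic_metrics(structure(list(tp = 24, fp = 11, fn = 11, tn = 69),
#'                              class = "two_by_two"))
#' @export
diagnostic_metrics <- function(tbl, conf.level = 0.95) {
  stopifnot(inherits(tbl, "two_by_two"))
  with(tbl, {
    if (tp + fp + fn + tn == 0) stop("all-zero table", call. = FALSE)
    one <- function(metric, x, n) {
      if (n == 0) {
        return(data.frame(metric = metric, estimate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_))
      }
      ci <- 100 * clopper_pearson(x, n, conf.level)
      data.frame(metric = metric, estimate = 100 * x / n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]))
    }
    rbind(one("sensitivity", tp, tp + fn),
          one("specificity", tn, fp + tn),
          one("ppv", tp, tp + fp),
          one("npv", tn, tn + fn))
  })
}

#' Threshold sweep for a rule-out cutoff
#'
#' For each cutoff k, counts the patients with score <= k (the patients a
#' rule-out at k would label low-risk) by outcome stratum, with percentages
#' of the whole cohort, and the sensitivity and specificity of the induced
#' rule "high-risk iff score > k". Sensitivity and specificity are rounded
#' to one decimal (half-to-even, matching how the published tables print).
#'
#' @param records cohort data frame with `hrel`.
#' @param score integer score per record (e.g. `records$gbs` or
#'   [combined_score()]).
#' @param cutoffs cutoff grid, default 0..17.
#' @return data frame with columns `cutoff`, `cum_with`, `pct_with`,
#'   `cum_without`, `pct_without`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(records, score, cutoffs = 0:17) {
  check_gbs_range(score, "score")
  stopifnot(length(score) == nrow(records))
  n <- nrow(records)
  n_with <- sum(records$hrel)
  n_without <- n - n_with
  rows <- lapply(cutoffs, function(k) {
    cw <- sum(score <= k & records$hrel)
    cwo <- sum(score <= k & !records$hrel)
    data.frame(cutoff = k,
               cum_with = cw, pct_with = pct1(cw, n),
               cum_without = cwo, pct_without = pct1(cwo, n),
               sensitivity = pct1(n_with - cw, n_with),
               specificity = pct1(cwo, n_without))
  })
  do.call(rbind, rows)
}

#' Sensitivity-constrained optimal rule-out threshold
#'
#' Picks the largest cutoff whose rule keeps sensitivity for high-risk
#' lesions at or above a floor (98% by default). The floor is asymmetric by
#' design: raising the cutoff beyond it would misclassify patients who need
#' endoscopic treatment, which is far costlier than an unnecessary
#' endoscopy.
#'
#' @param sweep output of [threshold_sweep()].
#' @param min_sensitivity sensitivity floor in percent, default 98.
#' @return the selected integer cutoff.
#' @examples
#' coh <- study_cohort()
#' select_optimal_threshold(threshold_sweep(coh, coh$gbs))  # 0
#' @export
select_optimal_threshold <- function(sweep, min_sensitivity = 98) {
  ok <- sweep$cutoff[sweep$sensitivity >= min_sensitivity]
  if (!length(ok)) {
    stop("no cutoff attains sensitivity >= ", min_sensitivity, "%",
         call. = FALSE)
  }
  max(ok)
}

#' Compare two proportions
#'
#' Two-sided chi-square (without continuity correction) or Fisher's exact
#' test for x1/n1 versus x2/n2.
#'
#' @param x1,n1,x2,n2 successes and totals in each group.
#' @param method `"chi_square"` or `"fisher"`.
#' @return two-sided p-value.
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                method = c("chi_square", "fisher")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2)
  if (method == "chi_square") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(tab)$p.value
  }
}

#' Compare two group means (Student's t-test)
#'
#' Pooled-variance two-sample t-test, two-sided.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return two-sided p-value.
#' @export
compare_means <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(1)
    stop("both groups have zero variance; t statistic undefined",
         call. = FALSE)
  }
  stats::t.test(group_a, group_b, var.equal = TRUE)$p.value
}
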