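#' Combined GBS + nasogastric-aspirate score
#'
#' The continuous form of the triage rule: a bloody aspirate adds 23 points
#' to the Glasgow-Blatchford score, with the total capped at 23, so every
#' bloody-aspirate patient scores 23 and every non-bloody patient keeps
#' their GBS. This is the score fed to ROC analysis.
#'
#' @param gbs integer GBS in 0..23.
#' @param nga NGA categories (see [nga_is_bloody()]) or a logical
#'   bloody-aspirate indicator; recycled against `gbs`.
#' @return integer vector of combined scores in 0..23.
#' @examples
#' combined_score(5, "non_bloody")  # 5
#' combined_score(5, "bloody")      # 23
#' combined_score(0, "bloody")      # 23
#' @export
combined_score <- function(gbs, nga) {
  gbs <- check_gbs_range(gbs)
  bloody <- if (is.logical(nga)) nga else nga_is_bloody(nga)
  n <- max(length(gbs), length(bloody))
  gbs <- rep_len(gbs, n)
  bloody <- rep_len(bloody, n)
  as.integer(pmin(gbs + 23L * bloody, 23L))
}

#' Two-way triage classification
#'
#' Classifies a patient as `low_risk` exactly when the aspirate is
#' non-bloody and the GBS does not exceed the threshold; all other patients
#' (bloody aspirate, or GBS above the threshold) are `high_risk` and, under
#' the proposed management pathway, candidates for emergent endoscopy.
#' Equivalent to thresholding [combined_score()] at the same cutoff.
#'
#' @param gbs integer GBS in 0..23.
#' @param nga NGA categories or logical bloody indicator.
#' @param threshold integer rule-out cutoff in 0..22 (a threshold of 23
#'   would label bloody-aspirate patients low-risk, defeating the cap, and
#'   is rejected).
#' @return factor with levels `low_risk`, `high_risk`.
#' @examples
#' classify_patient(9, "non_bloody", 9)   # low_risk
#' classify_patient(10, "non_bloody", 9)  # high_risk
#' classify_patient(0, "bloody", 9)       # high_risk
#' @export
classify_patient <- function(gbs, nga, threshold) {
  gbs <- check_gbs_range(gbs)
  if (length(threshold) != 1L || threshold != round(threshold) ||
      threshold < 0 || threshold > 22) {
    stop("'threshold' must be a single integer in [0, 22]", call. = FALSE)
  }
  low <- combined_score(gbs, nga) <= threshold
  factor(ifelse(low, "low_risk", "high_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Stratify a cohort into low- and high-risk groups
#'
#' Applies either the combined rule (non-bloody aspirate and GBS <=
#' threshold) or the GBS-only rule (GBS <= threshold, aspirate ignored) and
#' counts the two groups.
#'
#' @param records cohort data frame with `gbs` and `nga`.
#' @param threshold integer rule-out cutoff.
#' @param rule `"combined"` (default) or `"gbs_only"`.
#' @return data frame with one row per risk class: `n` and `pct` (half-up,
#'   one decimal) of all records.
#' @examples
#' coh <- study_cohort()
#' stratify_cohort(coh, 9)                       # 27 low-risk (23.5%)
#' stratify_cohort(coh, 0, rule = "gbs_only")    # 3 low-risk (2.6%)
#' @export
stratify_cohort <- function(records, threshold,
                            rule = c("combined", "gbs_only")) {
  rule <- match.arg(rule)
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(risk = c("low_risk", "high_risk"),
                      n = c(0L, 0L), pct = c(NA_real_, NA_real_)))
  }
  bloody <- if (rule == "combined") nga_is_bloody(records$nga) else FALSE
  cls <- classify_patient(records$gbs, bloody, threshold)
  tab <- table(cls)
  data.frame(risk = names(tab),
             n = as.integer(tab),
             pct = pct1(as.integer(tab), n))
}
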