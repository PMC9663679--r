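#' Calibrate an integer score to predicted outcome probabilities
#'
#' Fits a univariate logistic regression of the outcome on the score and
#' returns the fitted probabilities — the standard way to place two scores
#' on a common risk scale before computing reclassification statistics.
#' If the fit is separated (some fitted probabilities numerically 0 or 1,
#' so the MLE diverges), the fit is flagged and rank-based pseudo-risks
#' `rank(score) / (n + 1)` are returned instead; these preserve the score
#' ordering, which is all NRI uses.
#'
#' @param scores integer scores.
#' @param outcome logical outcome, both classes present.
#' @return numeric vector of probabilities, with attributes `coef` (the
#'   logistic coefficients, `NULL` under fallback) and `separated`.
#' @export
calibrate_risk <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  if (!any(outcome) || all(outcome)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ scores, family = stats::binomial())
  )
  p <- unname(stats::fitted(fit))
  eps <- 1e-8
  separated <- !fit$converged || any(p < eps) || any(p > 1 - eps)
  if (separated) {
    n <- length(scores)
    p <- rank(scores, ties.method = "average") / (n + 1)
    attr(p, "coef") <- NULL
  } else {
    attr(p, "coef") <- stats::coef(fit)
  }
  attr(p, "separated") <- separated
  p
}

#' Continuous net reclassification improvement
#'
#' Compares per-patient risks under a new model against an old one.
#' Among events, upward risk movement is credited and downward movement
#' penalized; among non-events the signs are reversed; ties contribute
#' nothing:
#' \deqn{NRI = [P(\uparrow|D=1) - P(\downarrow|D=1)] +
#'             [P(\downarrow|D=0) - P(\uparrow|D=0)]}
#' Each component lies in [-1, 1], the total in [-2, 2].
#'
#' @param p_old,p_new per-patient risks (or any monotone risk proxies,
#'   e.g. the raw scores) under the old and new model, same patient order.
#' @param outcome logical outcome per patient.
#' @return object of class `reclass`: `nri_events`, `nri_nonevents`,
#'   `nri_total`.
#' @export
continuous_nri <- function(p_old, p_new, outcome) {
  stopifnot(length(p_old) == length(outcome),
            length(p_new) == length(outcome))
  outcome <- as.logical(outcome)
  if (!any(outcome) || all(outcome)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  delta <- sign(p_new - p_old)
  ev <- mean(delta[outcome])     # P(up|event) - P(down|event)
  ne <- -mean(delta[!outcome])   # P(down|nonevent) - P(up|nonevent)
  structure(list(nri_events = ev, nri_nonevents = ne, nri_total = ev + ne),
            class = "reclass")
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes between the new and old model:
#' \deqn{IDI = [\bar p_{new|D=1} - \bar p_{new|D=0}] -
#'             [\bar p_{old|D=1} - \bar p_{old|D=0}]}
#'
#' @inheritParams continuous_nri
#' @return object of class `reclass` with field `idi` and the four stratum
#'   means (`mean_new_events`, `mean_new_nonevents`, `mean_old_events`,
#'   `mean_old_nonevents`).
#' @export
idi <- function(p_old, p_new, outcome) {
  stopifnot(length(p_old) == length(outcome),
            length(p_new) == length(outcome))
  outcome <- as.logical(outcome)
  if (!any(outcome) || all(outcome)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  m <- list(mean_new_events = mean(p_new[outcome]),
            mean_new_nonevents = mean(p_new[!outcome]),
            mean_old_events = mean(p_old[outcome]),
            mean_old_nonevents = mean(p_old[!outcome]))
  structure(c(list(idi = (m$mean_new_events - m$mean_new_nonevents) -
                     (m$mean_old_events - m$mean_old_nonevents)), m),
            class = "reclass")
}

#' @export
print.reclass <- function(x, digits = 3, ...) {
  for (f in intersect(c("nri_events", "nri_nonevents", "nri_total", "idi"),
                      names(x))) {
    cat(sprintf("  %-13s %+.*f\n", f, digits, x[[f]]))
  }
  invisible(x)
}

#' Reclassification analysis of the combined score against the GBS
#'
#' Full added-value analysis: calibrates both scores to risks via
#' [calibrate_risk()] (or uses the raw scores directly), computes
#' continuous NRI and IDI, and attaches bootstrap percentile confidence
#' intervals from resampling patients with replacement.
#'
#' @param records cohort data frame with `gbs`, `nga`, `hrel`.
#' @param raw_scores if `TRUE`, skip logistic calibration and use the raw
#'   scores as risk proxies (NRI is unchanged by any monotone transform;
#'   IDI is then on the score scale and not comparable across cohorts).
#' @param n_boot number of bootstrap resamples for the CIs (0 disables).
#' @param conf.level confidence level, default 0.95.
#' @param seed integer seed for the bootstrap, for reproducibility.
#' @return list with `nri`, `idi`, and (if `n_boot > 0`) `ci`, a data
#'   frame of percentile intervals.
#' @export
compare_reclassification <- function(records, raw_scores = FALSE,
                                     n_boot = 1000, conf.level = 0.95,
                                     seed = 1L) {
  check_gbs_range(records$gbs)
  new_score <- combined_score(records$gbs, records$nga)
  risks <- function(df, sc_old, sc_new) {
    if (raw_scores) list(old = sc_old, new = sc_new)
    else list(old = calibrate_risk(sc_old, df$hrel),
              new = calibrate_risk(sc_new, df$hrel))
  }
  r <- risks(records, records$gbs, new_score)
  out <- list(nri = continuous_nri(r$old, r$new, records$hrel),
              idi = idi(r$old, r$new, records$hrel))
  if (n_boot > 0) {
    stat <- function(df) {
      sc_new <- combined_score(df$gbs, df$nga)
      rr <- risks(df, df$gbs, sc_new)
      nri <- continuous_nri(rr$old, rr$new, df$hrel)
      c(nri_events = nri$nri_events, nri_nonevents = nri$nri_nonevents,
        nri_total = nri$nri_total,
        idi = idi(rr$old, rr$new, df$hrel)$idi)
    }
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    draws <- replicate(n_boot, {
      repeat {  # resample until both outcome classes present
        idx <- sample.int(nrow(records), replace = TRUE)
        if (length(unique(records$hrel[idx])) == 2L) break
      }
      stat(records[idx, , drop = FALSE])
    })
    alpha <- 1 - conf.level
    qs <- apply(draws, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2))
    out$ci <- data.frame(statistic = colnames(qs),
                         ci_low = qs[1, ], ci_high = qs[2, ],
                         row.names = NULL)
  }
  out
}
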