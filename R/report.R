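#' Score histograms by outcome stratum
#'
#' Counts patients at each GBS value 0..23 with and without a high-risk
#' lesion, overall and split by aspirate appearance — the tabular form of
#' the stacked histograms used to display the cohort.
#'
#' @param records cohort data frame with `gbs`, `nga`, `hrel`.
#' @return list of three 24 x 2 integer matrices (`all`, `bloody`,
#'   `non_bloody`), rows named by score, columns `with_hrel` /
#'   `without_hrel`. `all` equals `bloody + non_bloody` elementwise.
#' @export
render_histograms <- function(records) {
  check_gbs_range(records$gbs)
  bloody <- nga_is_bloody(records$nga)
  count_matrix <- function(sel) {
    m <- vapply(list(records$hrel & sel, !records$hrel & sel),
                function(g) tabulate(records$gbs[g] + 1L, nbins = 24L),
                integer(24))
    dimnames(m) <- list(score = 0:23,
                        c("with_hrel", "without_hrel"))
    m
  }
  list(all = count_matrix(rep(TRUE, nrow(records))),
       bloody = count_matrix(bloody),
       non_bloody = count_matrix(!bloody))
}

#' Run the complete risk-stratification analysis
#'
#' Executes the whole pipeline on a cohort: scoring (if raw variables are
#' present and `gbs` is absent), threshold sweeps for the GBS and the
#' combined score, sensitivity-constrained threshold selection, low-/
#' high-risk stratification under both rules with a chi-square comparison,
#' diagnostic metrics with exact CIs, ROC/AUC with the paired DeLong test,
#' reclassification statistics (NRI/IDI), the group comparison of GBS by
#' outcome, and the score histograms.
#'
#' @param records cohort data frame (see [cohort]); must be non-empty and
#'   carry `nga` and `hrel`.
#' @param min_sensitivity sensitivity floor (%) for threshold selection.
#' @param cutoffs cutoff grid for the sweeps.
#' @param n_boot bootstrap resamples for the NRI/IDI confidence intervals.
#' @param seed seed for the bootstrap.
#' @param quiet suppress per-stage progress messages.
#' @return object of class `report_bundle`: `summary`, `sweep_gbs`,
#'   `sweep_algorithm`, `thresholds` (selected cutoffs), `stratification`
#'   (low-risk proportions under both rules and the chi-square p-value),
#'   `metrics_gbs`, `metrics_algorithm`, `metrics_bloody_nga`, `roc`
#'   (paired DeLong test, containing both `roc_auc` fits), `reclass`,
#'   `gbs_by_outcome` (means, SDs, t-test p), `histograms`.
#' @export
run_full_analysis <- function(records, min_sensitivity = 98,
                              cutoffs = 0:17, n_boot = 1000, seed = 1L,
                              quiet = FALSE) {
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  if (is.null(records) || nrow(records) == 0L) {
    stop("cohort_data stage: empty cohort", call. = FALSE)
  }
  if (!"gbs" %in% names(records)) {
    say("gbs_scoring", "computing GBS for %d records", nrow(records))
    records <- score_cohort(records)
  }
  check_gbs_range(records$gbs)
  say("cohort_data", "%d records, %d with high-risk lesions",
      nrow(records), sum(records$hrel))

  bloody <- nga_is_bloody(records$nga)
  algo <- combined_score(records$gbs, records$nga)

  say("diagnostic_eval", "threshold sweeps over %d cutoffs",
      length(cutoffs))
  sweep_gbs <- threshold_sweep(records, records$gbs, cutoffs)
  sweep_algo <- threshold_sweep(records, algo, cutoffs)
  thr_gbs <- select_optimal_threshold(sweep_gbs, min_sensitivity)
  thr_algo <- select_optimal_threshold(sweep_algo, min_sensitivity)

  strat_gbs <- stratify_cohort(records, thr_gbs, rule = "gbs_only")
  strat_algo <- stratify_cohort(records, thr_algo, rule = "combined")
  low_gbs <- strat_gbs$n[strat_gbs$risk == "low_risk"]
  low_algo <- strat_algo$n[strat_algo$risk == "low_risk"]
  p_strat <- compare_proportions(low_algo, nrow(records),
                                 low_gbs, nrow(records), "chi_square")

  metrics <- function(score, thr) {
    diagnostic_metrics(two_by_two(records, score > thr))
  }
  say("roc_delong", "paired AUC comparison")
  roc <- delong_paired_test(records$gbs, algo, records$hrel)

  say("reclassification", "NRI/IDI with %d bootstrap resamples", n_boot)
  reclass <- compare_reclassification(records, n_boot = n_boot, seed = seed)

  g1 <- records$gbs[records$hrel]
  g0 <- records$gbs[!records$hrel]
  gbs_by_outcome <- list(
    mean_with = mean(g1), sd_with = stats::sd(g1),
    mean_without = mean(g0), sd_without = stats::sd(g0),
    mean_overall = mean(records$gbs), sd_overall = stats::sd(records$gbs),
    p.value = compare_means(g1, g0))

  structure(list(
    summary = summarize_cohort(records),
    sweep_gbs = sweep_gbs,
    sweep_algorithm = sweep_algo,
    thresholds = c(gbs = thr_gbs, algorithm = thr_algo),
    stratification = list(gbs = strat_gbs, algorithm = strat_algo,
                          p.value = p_strat),
    metrics_gbs = metrics(records$gbs, thr_gbs),
    metrics_algorithm = metrics(algo, thr_algo),
    metrics_bloody_nga = diagnostic_metrics(two_by_two(records, bloody)),
    roc = roc,
    reclass = reclass,
    gbs_by_outcome = gbs_by_outcome,
    histograms = render_histograms(records)
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  n <- sum(x$histograms$all)
  cat("Risk-stratification report (", n, " patients)\n", sep = "")
  cat(sprintf("  Selected cutoffs: GBS <= %d, algorithm <= %d\n",
              x$thresholds["gbs"], x$thresholds["algorithm"]))
  la <- x$stratification$algorithm
  lg <- x$stratification$gbs
  cat(sprintf("  Low-risk: algorithm %d (%.1f%%) vs GBS %d (%.1f%%), p = %s\n",
              la$n[la$risk == "low_risk"], la$pct[la$risk == "low_risk"],
              lg$n[lg$risk == "low_risk"], lg$pct[lg$risk == "low_risk"],
              format.pval(x$stratification$p.value, digits = 3,
                          eps = 1e-16)))
  cat(sprintf("  AUC: GBS %.3f vs algorithm %.3f, DeLong p = %s\n",
              x$roc$auc_a, x$roc$auc_b,
              format.pval(x$roc$p.value, digits = 3, eps = 1e-16)))
  cat(sprintf("  NRI %.3f (events %.3f, non-events %.3f); IDI %.3f\n",
              x$reclass$nri$nri_total, x$reclass$nri$nri_events,
              x$reclass$nri$nri_nonevents, x$reclass$idi$idi))
  invisible(x)
}

#' Write a report bundle to TSV/JSON files
#'
#' Renders the tables of a [run_full_analysis()] bundle as TSV files plus
#' a JSON summary of the headline statistics in an output directory.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(df, name, comment) {
    p <- file.path(dir, name)
    con <- file(p, "w", encoding = "UTF-8")
    writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  wtsv(bundle$summary, "cohort_summary.tsv",
       "cohort characteristics by outcome stratum")
  wtsv(bundle$sweep_gbs, "sweep_gbs.tsv",
       "rule-out threshold sweep, GBS")
  wtsv(bundle$sweep_algorithm, "sweep_algorithm.tsv",
       "rule-out threshold sweep, combined GBS + NGA score")
  perf <- rbind(cbind(rule = "gbs", bundle$metrics_gbs),
                cbind(rule = "algorithm", bundle$metrics_algorithm),
                cbind(rule = "bloody_nga", bundle$metrics_bloody_nga))
  wtsv(perf, "performance.tsv",
       "diagnostic accuracy at the selected cutoffs (percent, exact CIs)")
  hist_df <- do.call(rbind, lapply(names(bundle$histograms), function(g) {
    m <- bundle$histograms[[g]]
    data.frame(group = g, score = 0:23, with_hrel = m[, 1],
               without_hrel = m[, 2])
  }))
  wtsv(hist_df, "histograms.tsv", "score distribution counts")
  headline <- list(
    n = sum(bundle$histograms$all),
    thresholds = as.list(bundle$thresholds),
    auc_gbs = bundle$roc$auc_a,
    auc_algorithm = bundle$roc$auc_b,
    delong_p = bundle$roc$p.value,
    low_risk_pct_gbs =
      bundle$stratification$gbs$pct[
        bundle$stratification$gbs$risk == "low_risk"],
    low_risk_pct_algorithm =
      bundle$stratification$algorithm$pct[
        bundle$stratification$algorithm$risk == "low_risk"],
    stratification_p = bundle$stratification$p.value,
    nri_total = bundle$reclass$nri$nri_total,
    idi = bundle$reclass$idi$idi
  )
  jp <- file.path(dir, "headline.json")
  jsonlite::write_json(headline, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
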