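#' @name cohort
#' @title Patient cohort data model
#'
#' @description
#' A cohort is an ordinary data frame with one row per emergency-department
#' patient. The canonical CSV dialect (UTF-8, comma-separated, header row,
#' booleans coded 0/1) uses the columns
#' `id, age, sex, hematemesis, melena, syncope, sbp, dbp, pulse,
#' hemoglobin_g_dl, bun_value, bun_unit, hepatic_disease, cardiac_failure,
#' nga, hrel, gbs`. Either `gbs` (an integer in 0..23) or the complete set
#' of raw variables needed by [compute_gbs()] must be present. The
#' nasogastric-aspirate column `nga` holds one of the four recorded
#' categories `bloody`, `coffee_ground`, `bile_like`, `clear`, or the
#' pre-binarized token `non_bloody` when only the binary classification is
#' known (as in cohorts reconstructed from published count tables).
#' `hrel` is the outcome label: a high-risk endoscopic lesion (Forrest
#' Ia/Ib/IIa ulcer or an actively spurting non-ulcer source) was found at
#' endoscopy.
NULL

NGA_CATEGORIES <- c("bloody", "coffee_ground", "bile_like", "clear")

#' Binarize nasogastric aspirate findings
#'
#' The triage rule only distinguishes bloody from non-bloody aspirates:
#' bright- or dark-red aspirates are `bloody`; coffee-ground, bile-like and
#' clear aspirates are `non_bloody`.
#'
#' @param nga character vector of aspirate categories (the four recorded
#'   categories or the already-binary `"non_bloody"`).
#' @return logical vector, `TRUE` where the aspirate is bloody.
#' @export
nga_is_bloody <- function(nga) {
  ok <- nga %in% c(NGA_CATEGORIES, "non_bloody")
  if (!all(ok)) {
    stop("unknown NGA category: ",
         paste(unique(nga[!ok]), collapse = ", "), call. = FALSE)
  }
  nga == "bloody"
}

#' Cumulative count table for an integer score
#'
#' Published threshold tables report, for each cutoff k, the number of
#' patients with score <= k separately for those with and without the
#' outcome. This constructor validates the two cumulative sequences
#' (non-decreasing, non-negative first differences) and records the group
#' totals taken from the final entries.
#'
#' @param cutoffs ordered integer cutoffs (the printed "<= k" rows).
#' @param cum_with cumulative counts among patients with the outcome.
#' @param cum_without cumulative counts among patients without the outcome.
#' @return an object of class `cumulative_table`.
#' @export
cumulative_table <- function(cutoffs, cum_with, cum_without) {
  cutoffs <- as.integer(cutoffs)
  cum_with <- as.integer(cum_with)
  cum_without <- as.integer(cum_without)
  if (length(cutoffs) != length(cum_with) ||
      length(cutoffs) != length(cum_without)) {
    stop("cutoffs and count columns must have equal length", call. = FALSE)
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  for (v in list(cum_with, cum_without)) {
    if (any(v < 0) || is.unsorted(v)) {
      stop("cumulative counts must be non-negative and non-decreasing",
           call. = FALSE)
    }
  }
  structure(
    list(cutoffs = cutoffs, cum_with = cum_with, cum_without = cum_without,
         totals = c(n_with = cum_with[length(cum_with)],
                    n_without = cum_without[length(cum_without)])),
    class = "cumulative_table"
  )
}

#' @export
print.cumulative_table <- function(x, ...) {
  cat("Cumulative count table (", length(x$cutoffs), " cutoffs; totals ",
      x$totals[1], " with / ", x$totals[2], " without outcome)\n", sep = "")
  print(data.frame(cutoff = x$cutoffs, cum_with = x$cum_with,
                   cum_without = x$cum_without), row.names = FALSE)
  invisible(x)
}

# Per-score counts (first differences) of a cumulative table.
per_score_counts <- function(tab) {
  list(with = diff(c(0L, tab$cum_with)),
       without = diff(c(0L, tab$cum_without)))
}

#' Published threshold tables of the development study
#'
#' Returns the cumulative count tables published for the 115-patient
#' development cohort: one for the Glasgow-Blatchford score over all
#' patients, and one for the combined algorithm score, whose cumulative
#' columns at cutoffs below 23 count only non-bloody patients (every bloody
#' patient's algorithm score is 23). Also returns the bloody-aspirate
#' counts by lesion status (24 with, 11 without a high-risk lesion), which
#' together with the two tables identify the full joint distribution of
#' (GBS, bloody aspirate, lesion status).
#'
#' @return a list with elements `gbs` and `algorithm` (both
#'   [cumulative_table()] objects) and `bloody_counts`
#'   (`c(n_with, n_without)`).
#' @export
study_tables <- function() {
  path <- system.file("extdata", "threshold_table_cumulative.tsv",
                      package = "gbsnga", mustWork = TRUE)
  raw <- utils::read.delim(path, comment.char = "#")
  list(
    gbs = cumulative_table(raw$cutoff, raw$gbs_cum_with, raw$gbs_cum_without),
    algorithm = cumulative_table(raw$cutoff, raw$algo_cum_with,
                                 raw$algo_cum_without),
    bloody_counts = c(n_with = 24L, n_without = 11L)
  )
}

#' Reconstruct a patient-level cohort from cumulative count tables
#'
#' Rebuilds the exact per-patient joint distribution of (GBS, bloody NGA,
#' outcome) from two published cumulative tables. The algorithm-score table
#' restricted to cutoffs below 23 counts only non-bloody patients, because
#' a bloody aspirate forces the algorithm score to 23 while a non-bloody
#' patient's algorithm score equals their GBS. Hence, per score value and
#' outcome stratum:
#'
#' 1. all-patient counts are first differences of the GBS table;
#' 2. non-bloody counts are first differences of the algorithm table;
#' 3. bloody counts are the difference (1) minus (2).
#'
#' One record per patient is materialized, deterministically ordered by
#' (outcome present first, bloody first, GBS ascending) with ids
#' `P001 ... Pnnn`.
#'
#' @param gbs_table [cumulative_table()] of GBS over all patients.
#' @param algo_table [cumulative_table()] of the algorithm score; its
#'   columns must count the non-bloody patients (cutoffs < 23).
#' @param bloody_counts integer vector `c(n_with, n_without)`: bloody-NGA
#'   patients with and without the outcome. Used to cross-check the
#'   reconstruction.
#' @return a cohort data frame with columns `id`, `gbs`, `nga`
#'   (`"bloody"`/`"non_bloody"`), `hrel` (logical).
#' @examples
#' tabs <- study_tables()
#' coh <- reconstruct_cohort(tabs$gbs, tabs$algorithm, tabs$bloody_counts)
#' nrow(coh)       # 115
#' sum(coh$hrel)   # 35
#' @export
reconstruct_cohort <- function(gbs_table, algo_table,
                               bloody_counts = c(24L, 11L)) {
  stopifnot(inherits(gbs_table, "cumulative_table"),
            inherits(algo_table, "cumulative_table"))
  if (!identical(gbs_table$cutoffs, algo_table$cutoffs)) {
    stop("tables must share the same cutoff grid", call. = FALSE)
  }
  bloody_counts <- as.integer(bloody_counts)
  if (any(algo_table$totals + bloody_counts != gbs_table$totals)) {
    stop("inconsistent tables: non-bloody totals plus bloody counts must ",
         "equal the overall totals", call. = FALSE)
  }
  all_c <- per_score_counts(gbs_table)
  nb_c <- per_score_counts(algo_table)
  bl_with <- all_c$with - nb_c$with
  bl_without <- all_c$without - nb_c$without
  if (any(bl_with < 0) || any(bl_without < 0)) {
    stop("inconsistent tables: algorithm-table count exceeds GBS-table ",
         "count at some score", call. = FALSE)
  }
  if (sum(bl_with) != bloody_counts[1] ||
      sum(bl_without) != bloody_counts[2]) {
    stop("inconsistent tables: reconstructed bloody counts disagree with ",
         "'bloody_counts'", call. = FALSE)
  }
  scores <- gbs_table$cutoffs
  block <- function(counts, hrel, bloody) {
    gbs <- rep.int(scores, counts)
    if (!length(gbs)) return(NULL)
    data.frame(gbs = as.integer(gbs),
               nga = if (bloody) "bloody" else "non_bloody",
               hrel = hrel)
  }
  out <- rbind(block(bl_with, TRUE, TRUE),
               block(nb_c$with, TRUE, FALSE),
               block(bl_without, FALSE, TRUE),
               block(nb_c$without, FALSE, FALSE))
  out <- out[order(-out$hrel, out$nga != "bloody", out$gbs), , drop = FALSE]
  out <- data.frame(id = sprintf("P%03d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate a cohort back into a cumulative count table
#'
#' Inverse of [reconstruct_cohort()] for one score: counts, at each cutoff,
#' the patients with score <= cutoff by outcome stratum. Restricting
#' `records` to non-bloody patients recovers the published algorithm-score
#' table.
#'
#' @param records cohort data frame with `hrel`.
#' @param score integer score per record.
#' @param cutoffs cutoff grid (default 0..17).
#' @return a [cumulative_table()].
#' @export
cumulative_counts <- function(records, score, cutoffs = 0:17) {
  stopifnot(length(score) == nrow(records))
  cw <- vapply(cutoffs, function(k) sum(score <= k & records$hrel), 0L)
  cwo <- vapply(cutoffs, function(k) sum(score <= k & !records$hrel), 0L)
  cumulative_table(cutoffs, cw, cwo)
}

#' Read a cohort CSV
#'
#' Reads and validates a cohort file in the canonical dialect (see
#' [cohort]). Rows violating an invariant are reported with their row
#' number; the whole read fails rather than silently dropping records.
#'
#' @param path path to a CSV file with a header row.
#' @return a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "nga", "hrel")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw_cols <- c("sex", "sbp", "pulse", "hemoglobin_g_dl", "bun_value",
                "bun_unit", "melena", "syncope", "hepatic_disease",
                "cardiac_failure")
  has_gbs <- "gbs" %in% names(df)
  has_raw <- all(raw_cols %in% names(df))
  if (!has_gbs && !has_raw) {
    stop("cohort file must carry either a 'gbs' column or all raw ",
         "variable columns (", paste(raw_cols, collapse = ", "), ")",
         call. = FALSE)
  }
  if ("bun_value" %in% names(df) && !"bun_unit" %in% names(df)) {
    stop("'bun_value' present without a 'bun_unit' declaration", call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)

  problems <- character(0)
  bad_nga <- !(df$nga %in% c(NGA_CATEGORIES, "non_bloody"))
  if (any(bad_nga)) {
    problems <- c(problems, sprintf("row %d: unknown nga category '%s'",
                                    which(bad_nga), df$nga[bad_nga]))
  }
  df$hrel <- as_logical_01(df$hrel, "hrel")
  for (col in intersect(c("hematemesis", "melena", "syncope",
                          "hepatic_disease", "cardiac_failure"), names(df))) {
    df[[col]] <- as_logical_01(df[[col]], col)
  }
  if (has_gbs) {
    g <- df$gbs
    bad_gbs <- !is.na(g) & (g != round(g) | g < 0 | g > 23)
    if (any(bad_gbs)) {
      problems <- c(problems,
                    sprintf("row %d: gbs=%s outside integer range [0, 23]",
                            which(bad_gbs), g[bad_gbs]))
    }
    if (anyNA(g) && !has_raw) {
      problems <- c(problems, sprintf("row %d: gbs missing and raw %s",
                                      which(is.na(g)),
                                      "variables unavailable"))
    }
  }
  if (length(problems)) {
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if (has_gbs) df$gbs <- as.integer(df$gbs)
  df
}

#' Write a cohort CSV
#'
#' Writes a cohort data frame in the canonical dialect: UTF-8, comma
#' separated, header, logicals coded 0/1. Byte-stable for a given cohort.
#'
#' @param records cohort data frame.
#' @param path output path.
#' @export
write_cohort <- function(records, path) {
  out <- records
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- round(out[[col]], 3)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The reconstructed development cohort
#'
#' Convenience accessor: reconstructs the 115-patient development cohort
#' from the published tables via [reconstruct_cohort()].
#'
#' @return cohort data frame (115 rows; 35 with a high-risk lesion).
#' @export
study_cohort <- function() {
  tabs <- study_tables()
  reconstruct_cohort(tabs$gbs, tabs$algorithm, tabs$bloody_counts)
}

#' Summarize a cohort by outcome stratum
#'
#' Tabulates counts (with percentages) for the binary variables and NGA
#' categories, and mean +/- SD for the numeric variables, overall and
#' within the strata with and without high-risk lesions.
#'
#' @param records cohort data frame; must carry `hrel`.
#' @return a data frame with one row per (variable, level) and columns
#'   `overall`, `with_hrel`, `without_hrel` formatted as `n (pct)` or
#'   `mean +/- sd`; numeric columns `n_overall` etc. kept alongside.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  strata <- list(overall = rep(TRUE, nrow(records)),
                 with_hrel = records$hrel,
                 without_hrel = !records$hrel)
  rows <- list()
  add <- function(variable, level, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level,
      overall = values[1], with_hrel = values[2], without_hrel = values[3],
      stringsAsFactors = FALSE)
  }
  count_row <- function(variable, level, flag) {
    vals <- vapply(strata, function(s) {
      n <- sum(flag & s)
      sprintf("%d (%.1f)", n, pct1(n, sum(s)))
    }, "")
    add(variable, level, vals)
  }
  num_row <- function(variable, x) {
    vals <- vapply(strata, function(s) {
      v <- x[s & !is.na(x)]
      if (!length(v)) return("-")
      if (length(v) == 1L) return(sprintf("%.1f", v))
      sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
    }, "")
    add(variable, "mean_sd", vals)
  }
  add("n", "count", vapply(strata, function(s) as.character(sum(s)), ""))
  for (col in intersect(c("age", "sbp", "dbp", "pulse", "hemoglobin_g_dl",
                          "bun_value", "gbs"), names(records))) {
    num_row(col, records[[col]])
  }
  for (col in intersect(c("hematemesis", "melena", "syncope",
                          "hepatic_disease", "cardiac_failure"),
                        names(records))) {
    count_row(col, "yes", records[[col]])
  }
  if ("sex" %in% names(records)) {
    count_row("sex", "male", records$sex == "male")
  }
  count_row("nga", "bloody", nga_is_bloody(records$nga))
  count_row("nga", "non_bloody", !nga_is_bloody(records$nga))
  for (cat in c("coffee_ground", "bile_like", "clear")) {
    if (any(records$nga == cat)) count_row("nga", cat, records$nga == cat)
  }
  do.call(rbind, rows)
}
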