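#' Convert blood urea nitrogen to mmol/L
#'
#' Laboratories report blood urea nitrogen (BUN) either in mg/dL (common in
#' North America and Japan) or in mmol/L (the unit the original
#' Glasgow-Blatchford criteria use). The molar conversion for urea nitrogen
#' is 1 mmol/L = 2.8 mg/dL.
#'
#' @param value numeric vector of BUN values, strictly positive.
#' @param unit unit of `value`: `"mg_dl"` or `"mmol_l"`.
#' @return numeric vector of BUN in mmol/L.
#' @examples
#' convert_bun(41.0, "mg_dl")   # cohort-mean BUN, approx 14.6 mmol/L
#' convert_bun(10.0, "mmol_l")  # pass-through
#' @export
convert_bun <- function(value, unit) {
  if (length(unit) != 1L || !unit %in% c("mg_dl", "mmol_l")) {
    stop("unknown BUN unit; use \"mg_dl\" or \"mmol_l\"", call. = FALSE)
  }
  if (any(!is.na(value) & value <= 0)) {
    stop("BUN values must be strictly positive", call. = FALSE)
  }
  if (unit == "mg_dl") value / 2.8 else value
}

#' Compute the Glasgow-Blatchford score
#'
#' Scores each patient with the original Glasgow-Blatchford admission-risk
#' criteria. Component points are:
#'
#' * BUN (mmol/L): 6.5 to <8.0 -> 2; 8.0 to <10.0 -> 3; 10.0 to <25.0 -> 4;
#'   >= 25.0 -> 6
#' * Hemoglobin (g/L), men: 120 to <130 -> 1; 100 to <120 -> 3; <100 -> 6
#' * Hemoglobin (g/L), women: 100 to <120 -> 1; <100 -> 6
#' * Systolic blood pressure (mmHg): 100-109 -> 1; 90-99 -> 2; <90 -> 3
#' * Pulse >= 100 /min -> 1; melena -> 1; syncope -> 2;
#'   hepatic disease -> 2; cardiac failure -> 2
#'
#' The total ranges from 0 to 23; higher totals indicate higher risk of
#' needing hospital-based intervention. Band edges are closed on the printed
#' endpoints (e.g. BUN exactly 6.5 scores 2, hemoglobin exactly 120 g/L in a
#' man scores 1).
#'
#' @param bun blood urea nitrogen in mmol/L (use [convert_bun()] first if
#'   measured in mg/dL).
#' @param hemoglobin hemoglobin in g/L.
#' @param sex `"male"` or `"female"` (recycled if length 1).
#' @param sbp systolic blood pressure in mmHg.
#' @param pulse heart rate in beats per minute.
#' @param melena,syncope,hepatic_disease,cardiac_failure logical flags.
#' @return a data frame of per-component points (`bun`, `hemoglobin`, `sbp`,
#'   `pulse`, `melena`, `syncope`, `hepatic`, `cardiac`) and the integer
#'   `total`, one row per patient.
#' @examples
#' compute_gbs(bun = 8.5, hemoglobin = 105, sex = "female", sbp = 105,
#'             pulse = 102, melena = TRUE, syncope = FALSE,
#'             hepatic_disease = FALSE, cardiac_failure = FALSE)$total  # 7
#' @export
compute_gbs <- function(bun, hemoglobin, sex, sbp, pulse,
                        melena, syncope, hepatic_disease, cardiac_failure) {
  n <- max(length(bun), length(hemoglobin), length(sex), length(sbp),
           length(pulse))
  bun <- rep_len(bun, n); hemoglobin <- rep_len(hemoglobin, n)
  sex <- rep_len(sex, n); sbp <- rep_len(sbp, n); pulse <- rep_len(pulse, n)
  melena <- rep_len(as.logical(melena), n)
  syncope <- rep_len(as.logical(syncope), n)
  hepatic_disease <- rep_len(as.logical(hepatic_disease), n)
  cardiac_failure <- rep_len(as.logical(cardiac_failure), n)

  if (!all(sex %in% c("male", "female"))) {
    stop("'sex' must be \"male\" or \"female\"", call. = FALSE)
  }
  if (any(bun <= 0 | hemoglobin <= 0 | sbp <= 0 | pulse <= 0, na.rm = TRUE)) {
    stop("physiologic inputs (bun, hemoglobin, sbp, pulse) must be positive",
         call. = FALSE)
  }

  bun_pts <- ifelse(bun >= 25, 6L,
             ifelse(bun >= 10, 4L,
             ifelse(bun >= 8,  3L,
             ifelse(bun >= 6.5, 2L, 0L))))
  hb_pts <- ifelse(sex == "male",
                   ifelse(hemoglobin < 100, 6L,
                   ifelse(hemoglobin < 120, 3L,
                   ifelse(hemoglobin < 130, 1L, 0L))),
                   ifelse(hemoglobin < 100, 6L,
                   ifelse(hemoglobin < 120, 1L, 0L)))
  sbp_pts <- ifelse(sbp < 90, 3L,
             ifelse(sbp < 100, 2L,
             ifelse(sbp < 110, 1L, 0L)))
  out <- data.frame(
    bun        = bun_pts,
    hemoglobin = hb_pts,
    sbp        = sbp_pts,
    pulse      = ifelse(pulse >= 100, 1L, 0L),
    melena     = ifelse(melena, 1L, 0L),
    syncope    = ifelse(syncope, 2L, 0L),
    hepatic    = ifelse(hepatic_disease, 2L, 0L),
    cardiac    = ifelse(cardiac_failure, 2L, 0L)
  )
  out$total <- as.integer(rowSums(out))
  stopifnot(all(out$total >= 0 & out$total <= 23))
  out
}

#' Score a cohort from raw clinical variables
#'
#' Computes the Glasgow-Blatchford score for every row of a cohort data
#' frame in the package's CSV dialect (see [read_cohort()]): hemoglobin is
#' taken from `hemoglobin_g_dl` (g/dL, converted internally to g/L) and BUN
#' from `bun_value` plus `bun_unit`.
#'
#' @param records cohort data frame carrying the raw variable columns.
#' @return `records` with a `gbs` column (overwritten if already present)
#'   and, if `breakdown = TRUE`, the per-component point columns prefixed
#'   `gbs_`.
#' @param breakdown if `TRUE`, also attach per-component points.
#' @export
score_cohort <- function(records, breakdown = FALSE) {
  needed <- c("sex", "sbp", "pulse", "hemoglobin_g_dl", "bun_value",
              "bun_unit", "melena", "syncope", "hepatic_disease",
              "cardiac_failure")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("cannot score cohort; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  units <- unique(records$bun_unit)
  if (!all(units %in% c("mg_dl", "mmol_l"))) {
    stop("bun_unit must be 'mg_dl' or 'mmol_l'", call. = FALSE)
  }
  bun <- ifelse(records$bun_unit == "mg_dl",
                records$bun_value / 2.8, records$bun_value)
  bd <- compute_gbs(
    bun = bun,
    hemoglobin = records$hemoglobin_g_dl * 10,
    sex = records$sex,
    sbp = records$sbp,
    pulse = records$pulse,
    melena = as_logical_01(records$melena, "melena"),
    syncope = as_logical_01(records$syncope, "syncope"),
    hepatic_disease = as_logical_01(records$hepatic_disease,
                                    "hepatic_disease"),
    cardiac_failure = as_logical_01(records$cardiac_failure,
                                    "cardiac_failure")
  )
  records$gbs <- bd$total
  if (breakdown) {
    comp <- bd[setdiff(names(bd), "total")]
    names(comp) <- paste0("gbs_", names(comp))
    records <- cbind(records, comp)
  }
  records
}
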