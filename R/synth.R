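# Synthetic cohort generation.
#
# The generator emulates the joint structure the triage problem needs:
# lesion prevalence, the conditional probability of a bloody aspirate in
# each outcome stratum, and per-stratum GBS distributions, then works
# backwards from each target GBS to raw clinical variables that score
# exactly that value.

# Per-component point sets and surrogate raw-value bands. Open-ended bands
# are bounded by physiologic surrogates so that a uniform draw is defined.
BUN_BANDS <- list(`0` = c(2.0, 6.5), `2` = c(6.5, 8), `3` = c(8, 10),
                  `4` = c(10, 25), `6` = c(25, 60))
HB_BANDS_MALE <- list(`0` = c(130, 170), `1` = c(120, 130),
                      `3` = c(100, 120), `6` = c(50, 100))
HB_BANDS_FEMALE <- list(`0` = c(120, 160), `1` = c(100, 120),
                        `6` = c(50, 100))
SBP_BANDS <- list(`0` = c(110, 160), `1` = c(100, 110),
                  `2` = c(90, 100), `3` = c(60, 90))
PULSE_BANDS <- list(`0` = c(55, 100), `1` = c(100, 140))

#' Enumerate Glasgow-Blatchford component-point decompositions
#'
#' All ways of writing a total score as a sum of admissible component
#' points: BUN in \{0,2,3,4,6\}, hemoglobin in \{0,1,3,6\} (men) or
#' \{0,1,6\} (women), systolic blood pressure in \{0,1,2,3\}, and the five
#' binary components (pulse, melena 0/1; syncope, hepatic disease, cardiac
#' failure 0/2).
#'
#' @param sex `"male"` or `"female"`.
#' @return integer matrix, one row per decomposition, with component
#'   columns and a `total` column. All totals 0..23 are feasible for
#'   either sex.
#' @export
gbs_decompositions <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  hb_set <- if (sex == "male") c(0L, 1L, 3L, 6L) else c(0L, 1L, 6L)
  g <- expand.grid(bun = c(0L, 2L, 3L, 4L, 6L), hemoglobin = hb_set,
                   sbp = 0:3, pulse = 0:1, melena = 0:1,
                   syncope = c(0L, 2L), hepatic = c(0L, 2L),
                   cardiac = c(0L, 2L), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  cbind(m, total = as.integer(rowSums(m)))
}

# Uniform draw on a measurement grid inside [lo, hi), e.g. integer mmHg
# for blood pressure. Staying on the grid keeps any later rounding of the
# CSV representation from crossing a band edge.
draw_in_band <- function(points, bands, step) {
  lo <- vapply(bands, `[`, 0, 1L)[as.character(points)]
  hi <- vapply(bands, `[`, 0, 2L)[as.character(points)]
  k <- pmax(1L, as.integer(round((hi - lo) / step)))
  offs <- floor(stats::runif(length(k)) * k)  # 0 .. k-1
  lo + step * offs
}

# Vectorized core: raw values realizing each target score, one patient per
# element of `target`, all of the same sex. Uses the current RNG stream.
inverse_raws_vec <- function(target, sex) {
  d <- gbs_decompositions(sex)
  rows <- integer(length(target))
  for (t in unique(target)) {
    cand <- which(d[, "total"] == t)
    if (!length(cand)) stop("no decomposition for target ", t, call. = FALSE)
    sel <- target == t
    rows[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE)]
  }
  pts <- d[rows, , drop = FALSE]
  hb_bands <- if (sex == "male") HB_BANDS_MALE else HB_BANDS_FEMALE
  data.frame(
    bun = draw_in_band(pts[, "bun"], BUN_BANDS, 0.1),
    hemoglobin = draw_in_band(pts[, "hemoglobin"], hb_bands, 1),
    sex = sex,
    sbp = draw_in_band(pts[, "sbp"], SBP_BANDS, 1),
    pulse = draw_in_band(pts[, "pulse"], PULSE_BANDS, 1),
    melena = pts[, "melena"] == 1L,
    syncope = pts[, "syncope"] == 2L,
    hepatic_disease = pts[, "hepatic"] == 2L,
    cardiac_failure = pts[, "cardiac"] == 2L,
    stringsAsFactors = FALSE
  )
}

#' Generate raw clinical variables realizing a target GBS
#'
#' Samples uniformly one component-point decomposition of the target score
#' (by exhaustive enumeration via [gbs_decompositions()]), then draws each
#' raw value uniformly inside the band that awards those points.
#' [compute_gbs()] applied to the result returns exactly `target_gbs`.
#' Uses the current RNG state.
#'
#' @param target_gbs integer in 0..23.
#' @param sex `"male"` or `"female"`.
#' @return one-row data frame of raw inputs for [compute_gbs()].
#' @export
inverse_generate_raws <- function(target_gbs, sex = "male") {
  check_gbs_range(target_gbs, "target_gbs")
  stopifnot(length(target_gbs) == 1L)
  inverse_raws_vec(target_gbs, match.arg(sex, c("male", "female")))
}

#' Synthetic cohort configuration
#'
#' Bundles the generator parameters. Defaults reproduce the development
#' study's structure: lesion prevalence 35/115 (30.4%), P(bloody aspirate |
#' lesion) 24/35 (68.6%), P(bloody | no lesion) 11/80 (13.8%), and
#' per-stratum GBS distributions that are normals with means 11.3 / 9.4
#' and SDs 3.7 / 4.2, discretized to the integers 0..23.
#'
#' @param n_patients cohort size.
#' @param prevalence_hrel probability of a high-risk endoscopic lesion.
#' @param p_bloody_given_hrel,p_bloody_given_no_hrel conditional
#'   probabilities of a bloody aspirate.
#' @param gbs_distribution either
#'   `list(type = "discretized_normal", mean_hrel, sd_hrel, mean_no_hrel,
#'   sd_no_hrel)` or `list(type = "empirical", weights = W)` where `W` is a
#'   24-row weight matrix (scores 0..23) with columns `hrel`, `no_hrel`,
#'   or with columns `hrel_bloody`, `hrel_non_bloody`, `no_hrel_bloody`,
#'   `no_hrel_non_bloody` to draw GBS jointly with aspirate status.
#' @param p_male probability a patient is male (used for the
#'   hemoglobin criteria and cohort realism).
#' @param seed integer seed; generation is byte-reproducible given the
#'   seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 115L,
                         prevalence_hrel = 35 / 115,
                         p_bloody_given_hrel = 24 / 35,
                         p_bloody_given_no_hrel = 11 / 80,
                         gbs_distribution = list(
                           type = "discretized_normal",
                           mean_hrel = 11.3, sd_hrel = 3.7,
                           mean_no_hrel = 9.4, sd_no_hrel = 4.2),
                         p_male = 73 / 115,
                         seed = 1L) {
  stop_if_not_prob(prevalence_hrel, "prevalence_hrel")
  stop_if_not_prob(p_bloody_given_hrel, "p_bloody_given_hrel")
  stop_if_not_prob(p_bloody_given_no_hrel, "p_bloody_given_no_hrel")
  stop_if_not_prob(p_male, "p_male")
  if (!gbs_distribution$type %in% c("discretized_normal", "empirical")) {
    stop("gbs_distribution$type must be 'discretized_normal' or ",
         "'empirical'", call. = FALSE)
  }
  if (gbs_distribution$type == "empirical") {
    w <- gbs_distribution$weights
    if (!is.matrix(w) || nrow(w) != 24L || any(w < 0) ||
        any(colSums(w) <= 0)) {
      stop("empirical weights must be a 24-row non-negative matrix with ",
           "normalizable columns", call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_hrel = prevalence_hrel,
                 p_bloody_given_hrel = p_bloody_given_hrel,
                 p_bloody_given_no_hrel = p_bloody_given_no_hrel,
                 gbs_distribution = gbs_distribution,
                 p_male = p_male,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Weights of the discretized, truncated normal on 0..23.
discretized_normal_weights <- function(mean, sd) {
  k <- 0:23
  w <- stats::pnorm(k + 0.5, mean, sd) - stats::pnorm(k - 0.5, mean, sd)
  w / sum(w)
}

sample_scores <- function(n, weights) {
  if (n == 0L) return(integer(0))
  sample(0:23, n, replace = TRUE, prob = weights)
}

#' Generate a synthetic emergency-department cohort
#'
#' Draws, per patient: lesion status from the prevalence; bloody-aspirate
#' status from the stratum-conditional probability; a GBS from the
#' configured stratum distribution; and then raw clinical variables that
#' realize exactly that GBS via [inverse_generate_raws()]. Non-bloody
#' aspirates are assigned a concrete category (coffee-ground / bile-like /
#' clear) in the development study's observed ratio, and age, diastolic
#' pressure and hematemesis are drawn independently for realism of the CSV
#' (they play no role in any score).
#'
#' @param config a [synth_config()].
#' @return cohort data frame in the canonical dialect (see [cohort]),
#'   including a `gbs` column guaranteed to equal [score_cohort()]'s
#'   recomputation.
#' @examples
#' coh <- generate_cohort(synth_config(n_patients = 200, seed = 42))
#' table(coh$hrel)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  n <- config$n_patients
  hrel <- stats::runif(n) < config$prevalence_hrel
  p_bloody <- ifelse(hrel, config$p_bloody_given_hrel,
                     config$p_bloody_given_no_hrel)
  bloody <- stats::runif(n) < p_bloody

  gd <- config$gbs_distribution
  gbs <- integer(n)
  if (gd$type == "discretized_normal") {
    w1 <- discretized_normal_weights(gd$mean_hrel, gd$sd_hrel)
    w0 <- discretized_normal_weights(gd$mean_no_hrel, gd$sd_no_hrel)
    gbs[hrel] <- sample_scores(sum(hrel), w1)
    gbs[!hrel] <- sample_scores(sum(!hrel), w0)
  } else {
    w <- gd$weights
    if (all(c("hrel", "no_hrel") %in% colnames(w))) {
      gbs[hrel] <- sample_scores(sum(hrel), w[, "hrel"])
      gbs[!hrel] <- sample_scores(sum(!hrel), w[, "no_hrel"])
    } else {
      cols <- c("hrel_bloody", "hrel_non_bloody",
                "no_hrel_bloody", "no_hrel_non_bloody")
      if (!all(cols %in% colnames(w))) {
        stop("empirical weights must have columns hrel/no_hrel or the ",
             "four stratum-by-aspirate columns", call. = FALSE)
      }
      grp <- paste0(ifelse(hrel, "hrel", "no_hrel"),
                    ifelse(bloody, "_bloody", "_non_bloody"))
      for (g in unique(grp)) {
        gbs[grp == g] <- sample_scores(sum(grp == g), w[, g])
      }
    }
  }

  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  raws <- data.frame(bun = numeric(n), hemoglobin = numeric(n),
                     sex = sex, sbp = numeric(n), pulse = numeric(n),
                     melena = logical(n), syncope = logical(n),
                     hepatic_disease = logical(n),
                     cardiac_failure = logical(n),
                     stringsAsFactors = FALSE)
  for (s in c("male", "female")) {
    sel <- sex == s
    if (any(sel)) raws[sel, ] <- inverse_raws_vec(gbs[sel], s)
  }

  nga <- character(n)
  nga[bloody] <- "bloody"
  n_nb <- sum(!bloody)
  nga[!bloody] <- sample(c("coffee_ground", "bile_like", "clear"), n_nb,
                         replace = TRUE, prob = c(52, 6, 22) / 80)

  out <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, 74.8, 18.3)), 18), 100),
    sex = raws$sex,
    hematemesis = stats::runif(n) < 66 / 115,
    melena = raws$melena,
    syncope = raws$syncope,
    sbp = raws$sbp,
    dbp = round(pmin(pmax(stats::rnorm(n, 66.1, 17.8), 30), 130), 1),
    pulse = raws$pulse,
    hemoglobin_g_dl = raws$hemoglobin / 10,
    bun_value = round(raws$bun, 2),
    bun_unit = "mmol_l",
    hepatic_disease = raws$hepatic_disease,
    cardiac_failure = raws$cardiac_failure,
    nga = nga,
    hrel = hrel,
    stringsAsFactors = FALSE
  )
  out <- score_cohort(out)
  if (!identical(out$gbs, as.integer(gbs))) {
    stop("internal error: generated raw variables do not reproduce the ",
         "target scores", call. = FALSE)
  }
  out
}
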