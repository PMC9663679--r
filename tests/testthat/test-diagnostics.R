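coh <- study_cohort()
algo <- combined_score(coh$gbs, coh$nga)

test_that("confusion counts match the published aspirate cross-table", {
  t_bloody <- two_by_two(coh, nga_is_bloody(coh$nga))
  expect_identical(unclass(t_bloody)[c("tp", "fp", "fn", "tn")],
                   list(tp = 24L, fp = 11L, fn = 11L, tn = 69L))
  t_none <- two_by_two(coh, function(df) rep(FALSE, nrow(df)))
  expect_identical(t_none$tp + t_none$fp, 0L)
  t_algo9 <- two_by_two(coh, algo > 9)
  expect_identical(unclass(t_algo9)[c("tp", "fp", "fn", "tn")],
                   list(tp = 35L, fp = 53L, fn = 0L, tn = 27L))
  expect_error(two_by_two(coh, c(TRUE, FALSE)), "one logical prediction")
})

test_that("diagnostic metrics and exact CIs reproduce published cells", {
  m <- diagnostic_metrics(two_by_two(coh, nga_is_bloody(coh$nga)))
  est <- round(m$estimate, 1)
  expect_equal(est[m$metric == "sensitivity"], 68.6)
  expect_equal(est[m$metric == "specificity"], 86.2)
  expect_equal(est[m$metric == "ppv"], 68.6)
  expect_equal(est[m$metric == "npv"], 86.2)

  # specificity of the GBS <= 0 rule-out: 3/80 with exact CI (0.8, 10.6)
  ci <- 100 * clopper_pearson(3, 80)
  expect_equal(round(unname(ci), 1), c(0.8, 10.6))

  perfect <- structure(list(tp = 1L, fp = 0L, fn = 0L, tn = 1L),
                       class = "two_by_two")
  expect_true(all(diagnostic_metrics(perfect)$estimate == 100))
  expect_error(
    diagnostic_metrics(structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                                 class = "two_by_two")),
    "all-zero")
})

test_that("Clopper-Pearson endpoints behave exactly at the boundaries", {
  expect_equal(clopper_pearson(0, 20)[["lower"]], 0)
  expect_equal(clopper_pearson(20, 20)[["upper"]], 1)
  # swapping successes and failures mirrors the interval
  for (x in c(0, 3, 9, 17)) {
    a <- clopper_pearson(x, 20)
    b <- clopper_pearson(20 - x, 20)
    expect_equal(unname(a), unname(1 - b[2:1]), tolerance = 1e-12)
  }
})

test_that("threshold sweeps reproduce every published table cell", {
  tabs <- study_tables()
  check_block <- function(sweep, tab, n_with, n_without) {
    expect_identical(sweep$cum_with, tab$cum_with)
    expect_identical(sweep$cum_without, tab$cum_without)
    for (i in seq_along(tab$cutoffs)) {
      sens <- round(100 * (n_with - tab$cum_with[i]) / n_with, 1)
      spec <- round(100 * tab$cum_without[i] / n_without, 1)
      expect_equal(sweep$sensitivity[i], sens)
      expect_equal(sweep$specificity[i], spec)
    }
  }
  check_block(threshold_sweep(coh, coh$gbs), tabs$gbs, 35, 80)
  # algorithm block: published cumulative columns count non-bloody patients
  sw_algo <- threshold_sweep(coh, algo)
  nb_with <- sw_algo$cum_with
  expect_identical(nb_with, tabs$algorithm$cum_with)
  expect_identical(sw_algo$cum_without, tabs$algorithm$cum_without)
  # spot-check printed sensitivity/specificity values
  expect_equal(sw_algo$sensitivity[sw_algo$cutoff == 9], 100)
  expect_equal(sw_algo$specificity[sw_algo$cutoff == 9], 33.8)
  sw_gbs <- threshold_sweep(coh, coh$gbs)
  expect_equal(sw_gbs$sensitivity[sw_gbs$cutoff == 15], 8.6)
  expect_equal(sw_gbs$specificity[sw_gbs$cutoff == 0], 3.8)
  expect_equal(sw_gbs$sensitivity[sw_gbs$cutoff == 12], 34.3)
})

test_that("the sensitivity floor picks the published optimal cutoffs", {
  expect_identical(select_optimal_threshold(threshold_sweep(coh, coh$gbs)),
                   0L)
  expect_identical(select_optimal_threshold(threshold_sweep(coh, algo)), 9L)
  all100 <- data.frame(cutoff = 0:5, sensitivity = 100)
  expect_identical(select_optimal_threshold(all100), 5L)
  none <- data.frame(cutoff = 0:5, sensitivity = 50)
  expect_error(select_optimal_threshold(none), "no cutoff")
})

test_that("proportion comparisons match published bounds and enumeration", {
  expect_lt(compare_proportions(27, 115, 3, 115, "chi_square"), 0.001)
  expect_equal(compare_proportions(4, 10, 4, 10, "fisher"), 1)
  expect_equal(compare_proportions(2, 5, 3, 5, "fisher"), 1)
  # Fisher equals direct hypergeometric enumeration on small tables
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    expect_equal(compare_proportions(x1, n1, x2, n2, "fisher"),
                 oracle_fisher(x1, n1 - x1, x2, n2 - x2),
                 tolerance = 1e-9)
  }
})

test_that("group means compare by pooled-variance Student t-test", {
  p <- compare_means(coh$gbs[coh$hrel], coh$gbs[!coh$hrel])
  expect_equal(round(p, 2), 0.02)
  expect_equal(compare_means(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_means(c(2, 2), c(2, 2)), 1)
  expect_error(compare_means(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               "zero variance")
  expect_error(compare_means(1, c(1, 2)), "length")
})
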