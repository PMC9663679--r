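tabs <- study_tables()
coh <- study_cohort()

test_that("cumulative tables validate their invariants", {
  expect_s3_class(tabs$gbs, "cumulative_table")
  expect_identical(unname(tabs$gbs$totals), c(35L, 80L))
  expect_identical(unname(tabs$algorithm$totals), c(11L, 69L))
  expect_error(cumulative_table(0:2, c(0, 2, 1), c(0, 0, 0)),
               "non-decreasing")
  expect_error(cumulative_table(c(0, 0, 1), c(0, 1, 2), c(0, 0, 0)),
               "strictly increasing")
  expect_error(cumulative_table(0:1, c(0, 1, 2), c(0, 0)), "equal length")
})

test_that("reconstruction yields the exact published joint distribution", {
  expect_identical(nrow(coh), 115L)
  expect_identical(sum(coh$hrel), 35L)
  bloody <- nga_is_bloody(coh$nga)
  expect_identical(sum(bloody & coh$hrel), 24L)
  expect_identical(sum(bloody & !coh$hrel), 11L)
  expect_identical(sum(!bloody & coh$hrel), 11L)
  expect_identical(sum(!bloody & !coh$hrel), 69L)
  # patients without lesions at GBS exactly 3: cumulative 12 - 6
  expect_identical(sum(coh$gbs == 3 & !coh$hrel), 6L)
  # published group means reproduce at one decimal
  expect_equal(round(mean(coh$gbs[coh$hrel]), 1), 11.3)
  expect_equal(round(mean(coh$gbs[!coh$hrel]), 1), 9.4)
  expect_equal(round(mean(coh$gbs), 1), 10.0)
})

test_that("reconstruction round-trips to the input tables bit-for-bit", {
  back_gbs <- cumulative_counts(coh, coh$gbs)
  expect_identical(back_gbs$cum_with, tabs$gbs$cum_with)
  expect_identical(back_gbs$cum_without, tabs$gbs$cum_without)
  nb <- coh[!nga_is_bloody(coh$nga), ]
  back_algo <- cumulative_counts(nb, nb$gbs)
  expect_identical(back_algo$cum_with, tabs$algorithm$cum_with)
  expect_identical(back_algo$cum_without, tabs$algorithm$cum_without)
})

test_that("reconstruction is deterministic with documented id order", {
  again <- reconstruct_cohort(tabs$gbs, tabs$algorithm, tabs$bloody_counts)
  expect_identical(again, coh)
  expect_identical(coh$id, sprintf("P%03d", 1:115))
  # lesion-positive first, bloody before non-bloody, GBS ascending
  expect_true(all(diff(coh$hrel) <= 0))
  first_block <- coh[coh$hrel & nga_is_bloody(coh$nga), "gbs"]
  expect_true(!is.unsorted(first_block))
})

test_that("inconsistent tables are rejected", {
  bad_algo <- cumulative_table(tabs$algorithm$cutoffs,
                               pmin(tabs$algorithm$cum_with + 2, 13),
                               tabs$algorithm$cum_without)
  expect_error(
    reconstruct_cohort(tabs$gbs, bad_algo, c(22L, 11L)),
    "inconsistent tables")
  expect_error(
    reconstruct_cohort(tabs$gbs, tabs$algorithm, c(20L, 15L)),
    "totals")
})

test_that("the shipped fixture CSV equals the reconstruction", {
  fx <- read_cohort(study_fixture_path())
  expect_identical(nrow(fx), 115L)
  expect_identical(fx$gbs, coh$gbs)
  expect_identical(fx$hrel, coh$hrel)
  expect_identical(fx$nga, coh$nga)
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(back$gbs, coh$gbs)
  expect_identical(back$hrel, coh$hrel)
  # byte-stable for a fixed cohort
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_cohort validates structure and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,nga,hrel,gbs", path)
  expect_identical(nrow(read_cohort(path)), 0L)

  writeLines(c("id,nga,hrel,gbs", "P1,bloody,1,24"), path)
  expect_error(read_cohort(path), "row 1.*\\[0, 23\\]")

  writeLines(c("id,nga,hrel,gbs", "P1,sparkling,0,3"), path)
  expect_error(read_cohort(path), "unknown nga")

  writeLines(c("id,hrel,gbs", "P1,0,3"), path)
  expect_error(read_cohort(path), "required column")

  writeLines(c("id,nga,hrel", "P1,clear,0"), path)
  expect_error(read_cohort(path), "gbs")
})

test_that("summaries reproduce the published aspirate proportions", {
  s <- summarize_cohort(coh)
  bl <- s[s$variable == "nga" & s$level == "bloody", ]
  expect_identical(bl$overall, "35 (30.4)")
  expect_identical(bl$with_hrel, "24 (68.6)")
  expect_identical(bl$without_hrel, "11 (13.8)")
  nb <- s[s$variable == "nga" & s$level == "non_bloody", ]
  expect_identical(nb$overall, "80 (69.6)")

  one <- summarize_cohort(coh[1, ])
  expect_identical(one[one$variable == "gbs", "overall"],
                   sprintf("%.1f", coh$gbs[1]))  # SD absent for n = 1
  expect_error(summarize_cohort(coh[0, ]), "empty")
})
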