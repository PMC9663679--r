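test_that("worked examples score correctly", {
  healthy <- compute_gbs(bun = 5.0, hemoglobin = 145, sex = "male",
                         sbp = 120, pulse = 80, melena = FALSE,
                         syncope = FALSE, hepatic_disease = FALSE,
                         cardiac_failure = FALSE)
  expect_identical(healthy$total, 0L)

  maximal <- compute_gbs(bun = 30, hemoglobin = 95, sex = "male",
                         sbp = 85, pulse = 110, melena = TRUE,
                         syncope = TRUE, hepatic_disease = TRUE,
                         cardiac_failure = TRUE)
  expect_identical(maximal$total, 23L)
  expect_identical(unlist(maximal[1, 1:8], use.names = FALSE),
                   c(6L, 6L, 3L, 1L, 1L, 2L, 2L, 2L))

  # 3 (bun 8.5) + 1 (female hb 105) + 1 (sbp 105) + 1 (pulse) + 1 (melena)
  mixed <- compute_gbs(bun = 8.5, hemoglobin = 105, sex = "female",
                       sbp = 105, pulse = 102, melena = TRUE,
                       syncope = FALSE, hepatic_disease = FALSE,
                       cardiac_failure = FALSE)
  expect_identical(mixed$total, 7L)
})

test_that("BUN unit conversion divides mg/dL by 2.8", {
  expect_equal(convert_bun(2.8, "mg_dl"), 1.0)
  expect_equal(convert_bun(10.0, "mmol_l"), 10.0)
  # cohort-mean BUN of 41 mg/dL lands in the 10-25 mmol/L band (4 points)
  bun <- convert_bun(41.0, "mg_dl")
  expect_equal(bun, 41 / 2.8)
  pts <- compute_gbs(bun = bun, hemoglobin = 145, sex = "male", sbp = 120,
                     pulse = 80, melena = FALSE, syncope = FALSE,
                     hepatic_disease = FALSE, cardiac_failure = FALSE)
  expect_identical(pts$bun, 4L)
  expect_error(convert_bun(5, "mg"), "unknown BUN unit")
  expect_error(convert_bun(-1, "mg_dl"), "positive")
})

test_that("scorer agrees with the independent band-table oracle on a grid", {
  grid <- expand.grid(
    bun = c(3, 6.4, 6.5, 7.9, 8, 9.9, 10, 24.9, 25, 40),
    hb = c(80, 99, 100, 119, 120, 129, 130, 150),
    sex = c("male", "female"),
    sbp = c(70, 89, 90, 99, 100, 109, 110, 140),
    pulse = c(80, 99, 100),
    stringsAsFactors = FALSE
  )
  flags <- rbind(c(0, 0, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1))
  for (f in seq_len(nrow(flags))) {
    got <- compute_gbs(grid$bun, grid$hb, grid$sex, grid$sbp, grid$pulse,
                       melena = flags[f, 1] == 1, syncope = flags[f, 2] == 1,
                       hepatic_disease = flags[f, 3] == 1,
                       cardiac_failure = flags[f, 4] == 1)$total
    want <- mapply(oracle_gbs, grid$bun, grid$hb, grid$sex, grid$sbp,
                   grid$pulse, flags[f, 1], flags[f, 2], flags[f, 3],
                   flags[f, 4])
    expect_identical(got, as.integer(want))
  }
})

test_that("worsening any single input never decreases the score", {
  set.seed(11)
  base <- data.frame(
    bun = runif(60, 2, 50), hb = runif(60, 60, 160),
    sex = sample(c("male", "female"), 60, TRUE),
    sbp = runif(60, 65, 150), pulse = runif(60, 60, 130)
  )
  score <- function(d, mel = FALSE) {
    compute_gbs(d$bun, d$hb, d$sex, d$sbp, d$pulse, mel, FALSE,
                FALSE, FALSE)$total
  }
  s0 <- score(base)
  worse <- list(
    transform(base, bun = bun + 5),
    transform(base, hb = pmax(hb - 15, 55)),
    transform(base, sbp = pmax(sbp - 12, 60)),
    transform(base, pulse = pulse + 25)
  )
  for (w in worse) expect_true(all(score(w) >= s0))
  expect_true(all(score(base, mel = TRUE) >= s0))
})

test_that("score_cohort converts units and validates columns", {
  df <- data.frame(
    sex = "male", sbp = 120, pulse = 80, hemoglobin_g_dl = 14.5,
    bun_value = 41.0, bun_unit = "mg_dl", melena = 0, syncope = 0,
    hepatic_disease = 0, cardiac_failure = 0
  )
  expect_identical(score_cohort(df)$gbs, 4L)  # only the BUN band fires
  bd <- score_cohort(df, breakdown = TRUE)
  expect_identical(bd$gbs_bun, 4L)
  expect_error(score_cohort(df[-1]), "missing columns")
  df$bun_unit <- "furlongs"
  expect_error(score_cohort(df), "bun_unit")
  df$bun_unit <- "mmol_l"
  df$sbp <- -5
  expect_error(score_cohort(df), "positive")
})
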