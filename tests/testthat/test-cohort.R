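test_that("control classification follows the good/poor conventions", {
  co <- function(st, tms, nibut) {
    eye_record("e", "p", "left", "female", 60, "lt1y", st, tms, nibut, TRUE,
               "PG:latanoprost:1:pgA")
  }
  all_good <- classify_control(co(12, 2, 15))
  expect_true(all(all_good[c("st_good", "tms_good", "nibut_good",
                             "overall_good")] == TRUE))
  all_poor <- classify_control(co(9, 4, 10))
  expect_true(all(all_poor[c("st_good", "tms_good", "nibut_good",
                             "overall_good")] == FALSE))
  # boundary values (ST = 10, TMS = 3, NIBUT = 14) are poor by default
  on_boundary <- classify_control(co(10, 3, 14))
  expect_true(all(on_boundary[c("st_good", "tms_good", "nibut_good")] == FALSE))
  # ... and good under the inclusive convention
  inclusive <- classify_control(co(10, 3, 14),
                                control_thresholds(boundary = "good"))
  expect_true(all(inclusive[c("st_good", "tms_good", "nibut_good")] == TRUE))
})

test_that("classification errors name a missing measurement", {
  bad <- tiny_cohort()
  bad$nibut_s[2] <- NA
  expect_error(classify_control(bad), "nibut_s")
})

test_that("control classification is monotone in each measurement", {
  set.seed(11)
  for (i in 1:50) {
    rec <- eye_record("e", "p", "left", "male", 60, "lt1y",
                      st_mm = runif(1, 0, 20), tms_score = sample(0:6, 1),
                      nibut_s = runif(1, 0, 25), TRUE, "PG:latanoprost:1:")
    base <- classify_control(rec)
    better <- rec
    better$st_mm <- rec$st_mm + runif(1, 0, 10)
    better$nibut_s <- rec$nibut_s + runif(1, 0, 10)
    better$tms_score <- max(0L, rec$tms_score - sample(0:3, 1))
    up <- classify_control(better)
    expect_true(all(!base$st_good | up$st_good))
    expect_true(all(!base$tms_good | up$tms_good))
    expect_true(all(!base$nibut_good | up$nibut_good))
  }
})

test_that("cohort summary matches an independent filter-and-count oracle", {
  study <- generate_cohort(cohort_config(n_eyes = 1000, seed = 31))
  ch <- study$cohort
  s <- summarize_cohort(ch)
  cls <- classify_control(ch)
  pick <- function(ind, lev) s$n[s$indicator == ind & s$level == lev]

  expect_equal(pick("sex", "female"), sum(ch$sex == "female"))
  expect_equal(pick("side", "left"), sum(ch$side == "left"))
  expect_equal(pick("control_st", "poor"), sum(cls$st_mm <= 10))
  expect_equal(pick("control_tms", "good"), sum(cls$tms_score < 3))
  expect_equal(pick("control_nibut", "good"), sum(cls$nibut_s > 14))
  expect_equal(pick("preservative", "free"), sum(ch$preservative_free))

  # mono = exactly one glaucoma line, counted from the raw therapy strings
  n_gl <- vapply(strsplit(ch$therapies, ";"), function(lines) {
    sum(grepl("^(PG|BB|CAI|A2A):", lines))
  }, integer(1))
  expect_equal(pick("therapy_type", "monotherapy"), sum(n_gl == 1))
  expect_equal(pick("therapy_type_free", "combination"),
               sum(n_gl >= 2 & ch$preservative_free))
  mono_pg <- sum(n_gl == 1 & grepl("(^|;)PG:", ch$therapies))
  expect_equal(pick("mono_class", "PG"), mono_pg)

  # every whole-cohort indicator partitions the 1000 eyes
  for (ind in c("sex", "side", "duration", "control_st", "control_tms",
                "control_nibut", "preservative", "therapy_type")) {
    expect_equal(sum(s$n[s$indicator == ind]), 1000)
  }
  # percentages are the one-decimal rounding of the exact fractions
  expect_equal(s$pct, round(100 * s$frac, 1))
})

test_that("degenerate cohorts summarise sensibly", {
  expect_error(summarize_cohort(tiny_cohort()[0, ]), "empty cohort")
  one <- summarize_cohort(tiny_cohort()[1, ])
  expect_equal(one$pct[one$indicator == "sex" & one$level == "female"], 100)
  expect_equal(one$pct[one$indicator == "mono_class" & one$level == "PG"], 100)
})

test_that("cohort CSV round-trips and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(reference_cohort(), f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(reference_cohort()))
  # write(read(f)) reproduces the file contents
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # meiboscore outside 0..6 is rejected with the field name
  bad <- tiny_cohort()
  bad$tms_score[1] <- 7L
  fbad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, fbad)
  expect_error(read_cohort(fbad), "tms_score")

  # header-only file gives an empty cohort
  fempty <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_cohort()[0, ], fempty)
  expect_equal(nrow(read_cohort(fempty)), 0)

  # a non-numeric measurement is reported with its row
  txt <- readLines(f)
  txt[3] <- sub("15,", "not_a_number,", txt[3], fixed = TRUE)
  fmal <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, fmal)
  expect_error(read_cohort(fmal), "row 2")
})

test_that("validation names the offending row and field", {
  bad_age <- tiny_cohort(); bad_age$age_years[2] <- 20L
  expect_error(validate_cohort(bad_age, mode = "study"), "row 2.*age_years")
  expect_silent(validate_cohort(bad_age, mode = "lenient"))

  no_glaucoma <- tiny_cohort()
  no_glaucoma$therapies[1] <- "AT:hypromellose:4:atX"
  expect_error(validate_cohort(no_glaucoma), "glaucoma line")

  bad_class <- tiny_cohort()
  bad_class$therapies[1] <- "XX:foo:1:pgA"
  expect_error(validate_cohort(bad_class), "drug class")
})

test_that("the fixture cohort reproduces the published marginal tallies", {
  s <- summarize_cohort(reference_cohort())
  pick <- function(ind, lev) s[s$indicator == ind & s$level == lev, ]
  expect_equal(pick("preservative", "free")$n, 20)
  expect_equal(pick("therapy_type", "monotherapy")$n, 34)
  expect_equal(pick("therapy_type_free", "monotherapy")$pct, 70)
  expect_equal(pick("therapy_type_non_free", "monotherapy")$n, 20)
  expect_equal(pick("mono_class", "PG")$n, 25)
  expect_equal(pick("combo_type", "PG+BB+CAI")$n, 9)
  expect_equal(pick("control_nibut", "good")$n, 2)
  expect_equal(pick("age_band", "61to70")$n, 28)
  expect_equal(pick("duration", "lt1y")$pct, 42.2)
})
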