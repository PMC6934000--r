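test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- cohort_config(n_eyes = 50, seed = 99)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$prices, s2$prices)
  s3 <- generate_cohort(cohort_config(n_eyes = 50, seed = 100))
  expect_false(identical(s1$cohort, s3$cohort))
  # caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate probabilities produce degenerate cohorts", {
  all_free <- generate_cohort(cohort_config(n_eyes = 40, seed = 3,
                                            p_preservative_free = 1))
  expect_true(all(all_free$cohort$preservative_free))
  all_mono <- generate_cohort(cohort_config(n_eyes = 40, seed = 3,
                                            p_mono_given_free = 1,
                                            p_mono_given_nonfree = 1))
  n_gl <- vapply(strsplit(all_mono$cohort$therapies, ";"), function(lines) {
    sum(grepl("^(PG|BB|CAI|A2A):", lines))
  }, integer(1))
  expect_true(all(n_gl == 1))
})

test_that("generated cohorts validate and measurements match sampled control flags", {
  study <- generate_cohort(cohort_config(n_eyes = 500, seed = 17))
  expect_silent(validate_cohort(study$cohort, mode = "study"))
  cls <- classify_control(study$cohort)
  # intervals are strictly on one side of each threshold, so classification
  # can never disagree with the sampled flags
  expect_false(any(cls$st_mm > 9.5 & cls$st_mm < 10.5))
  expect_false(any(cls$nibut_s > 13.5 & cls$nibut_s < 14.5))
  # every product referenced by a therapy line is priced
  lines <- therapy_lines(study$cohort)
  expect_true(all(lines$product_id %in% study$prices$product_id))
})

test_that("empirical proportions and cost medians recover the configuration", {
  study <- generate_cohort(cohort_config(n_eyes = 20000, seed = 23))
  ch <- study$cohort
  se <- function(p, n) sqrt(p * (1 - p) / n)

  p_free <- mean(ch$preservative_free)
  expect_lt(abs(p_free - 20 / 64), 4 * se(20 / 64, nrow(ch)))
  mono <- vapply(strsplit(ch$therapies, ";"), function(lines) {
    sum(grepl("^(PG|BB|CAI|A2A):", lines)) == 1
  }, logical(1))
  p_mono_free <- mean(mono[ch$preservative_free])
  expect_lt(abs(p_mono_free - 0.70), 4 * se(0.7, sum(ch$preservative_free)))

  cls <- classify_control(ch)
  for (pair in list(list(cls$st_good, 15 / 64), list(cls$tms_good, 23 / 64),
                    list(cls$nibut_good, 2 / 64))) {
    expect_lt(abs(mean(pair[[1]]) - pair[[2]]), 4 * se(pair[[2]], nrow(ch)))
  }

  costs <- eye_yearly_cost(ch, study$prices)
  m_free <- median(costs$glaucoma_cost[ch$preservative_free])
  m_nonfree <- median(costs$glaucoma_cost[!ch$preservative_free])
  expect_lt(abs(m_free - 320.97) / 320.97, 0.05)
  expect_lt(abs(m_nonfree - 322.14) / 322.14, 0.05)
  expect_lt(abs(median(costs$dry_eye_cost) - 179.93) / 179.93, 0.05)
})

test_that("the log-normal solver hits the requested median and SD", {
  for (case in list(c(321.77, 181), c(179.93, 9.36), c(50, 0))) {
    p <- lognormal_from_median_sd(case[1], case[2])
    expect_equal(exp(p$meanlog), case[1])
    # analytic SD of the fitted log-normal equals the target
    v <- (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
    expect_equal(sqrt(v), case[2], tolerance = 1e-9)
  }
})

test_that("configs validate, round-trip through YAML, and re-serialise identically", {
  expect_equal(default_config()$n_eyes, 64)
  expect_error(cohort_config(p_preservative_free = 1.2), "p_preservative_free")
  expect_error(cohort_config(n_eyes = 0), "n_eyes")
  expect_error(cohort_config(mono_class_weights = c(PG = -1, BB = 1, CAI = 0,
                                                    A2A = 0)),
               "mono_class_weights")
  expect_error(cohort_config(control_probs = c(ST = 0.1, TMS = 0.2)),
               "control_probs")

  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(default_config(), f)
  back <- read_cohort_config(f)
  expect_identical(unclass(back), unclass(default_config()))
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # a cohort generated from the re-read config is identical
  expect_identical(generate_cohort(back)$cohort,
                   generate_cohort(default_config())$cohort)
})
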