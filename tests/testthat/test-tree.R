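test_that("probabilities are exact maximum-likelihood proportions", {
  expect_identical(estimate_probability(20, 64), 0.3125)
  expect_identical(estimate_probability(0, 64), 0)
  expect_identical(estimate_probability(64, 64), 1)
  expect_error(estimate_probability(1, 0), "undefined")
  expect_error(estimate_probability(5, 4), "n_event")
})

test_that("tree validation reports violations without erroring", {
  ok <- handbuilt_tree()
  expect_length(validate_tree(ok), 0)

  bad_p <- decision_tree(
    strategy_node("A", chance_node("mix", list(
      branch(0.6, terminal_node("x", 1, 1)),
      branch(0.6, terminal_node("y", 1, 1))
    ))),
    strategy_node("B", terminal_node("z", 1, 1))
  )
  v <- validate_tree(bad_p)
  expect_length(v, 1)
  expect_match(v, "mix")

  bad_c <- decision_tree(
    strategy_node("A", terminal_node("x", -5, 1)),
    strategy_node("B", terminal_node("z", 1, 1))
  )
  expect_match(validate_tree(bad_c), "negative")
  expect_error(rollback(bad_c), "invalid tree")
})

test_that("roll-back handles degenerate trees", {
  single <- decision_tree(
    strategy_node("A", terminal_node("only", cost = 100, effect = 1)),
    strategy_node("B", terminal_node("only", cost = 50, effect = 0))
  )
  rb <- rollback(single)
  expect_equal(rb$expected_cost, c(100, 50))
  expect_equal(rb$expected_effect, c(1, 0))

  mid <- decision_tree(
    strategy_node("A", chance_node("c", list(
      branch(0.5, terminal_node("x", 100, 0)),
      branch(0.5, terminal_node("y", 200, 1))
    ))),
    strategy_node("B", terminal_node("z", 0, 0))
  )
  rbm <- rollback(mid)
  expect_equal(rbm$expected_cost[1], 150)
  expect_equal(rbm$expected_effect[1], 0.5)
})

test_that("roll-back equals path enumeration on random trees", {
  set.seed(101)
  for (i in 1:60) {
    tr <- random_ce_tree(max_depth = 4)
    rb <- rollback(tr)
    or <- path_enumeration_oracle(tr)
    expect_equal(rb$expected_cost, or$expected_cost, tolerance = 1e-9)
    expect_equal(rb$expected_effect, or$expected_effect, tolerance = 1e-9)
    # expected values lie within the leaf payoff range
    paths <- enumerate_paths(tr)
    for (s in unique(paths$strategy)) {
      ps <- paths[paths$strategy == s, ]
      expect_gte(rb$expected_cost[rb$strategy == s], min(ps$cost) - 1e-9)
      expect_lte(rb$expected_cost[rb$strategy == s], max(ps$cost) + 1e-9)
      expect_gte(rb$expected_effect[rb$strategy == s], min(ps$effect) - 1e-9)
      expect_lte(rb$expected_effect[rb$strategy == s], max(ps$effect) + 1e-9)
    }
  }
})

test_that("roll-back is linear in leaf costs", {
  set.seed(7)
  tr <- random_ce_tree(3)
  scale_costs <- function(node, k) {
    if (node$type == "terminal") { node$cost <- node$cost * k; return(node) }
    node$branches <- lapply(node$branches, function(b) {
      b$node <- scale_costs(b$node, k); b
    })
    node
  }
  tr2 <- tr
  tr2$strategies <- lapply(tr$strategies, function(s) {
    s$root <- scale_costs(s$root, 3); s
  })
  expect_equal(rollback(tr2)$expected_cost, 3 * rollback(tr)$expected_cost)
  expect_equal(rollback(tr2)$expected_effect, rollback(tr)$expected_effect)
})

test_that("the cohort-built tree mirrors the cohort proportions and costs", {
  ch <- reference_cohort(); pr <- example_price_list()
  tr <- build_tree_from_cohort(ch, pr, effect_measure = "TMS")
  expect_length(validate_tree(tr), 0)
  paths <- enumerate_paths(tr)

  # P(monotherapy | preservative-free) = 14/20
  p_mono_free <- sum(paths$probability[paths$strategy == "preservative-free" &
                                         grepl("/monotherapy/", paths$path)])
  expect_equal(p_mono_free, 0.70, tolerance = 1e-12)

  # roll-back reproduces the arm-wise mean total yearly cost
  costs <- eye_yearly_cost(ch, pr)
  rb <- rollback(tr)
  expect_equal(rb$expected_cost[rb$strategy == "preservative-free"],
               mean(costs$glaucoma_cost[costs$preservative_free] +
                      costs$dry_eye_cost[costs$preservative_free]),
               tolerance = 1e-9)
  # ... and the arm-wise good-control proportion as its effect
  cls <- classify_control(ch)
  expect_equal(rb$expected_effect[rb$strategy == "preservative non-free"],
               mean(cls$tms_good[!cls$preservative_free]), tolerance = 1e-9)
})

test_that("a single-stratum cohort collapses to one path per strategy", {
  ch <- dplyr::bind_rows(lapply(1:4, function(i) {
    eye_record(paste0("m", i), paste0("p", i), "left", "female", 60, "lt1y",
               12, 2, 15, i <= 2,
               sprintf("PG:latanoprost:2:%s", if (i <= 2) "pgA" else "pgB"))
  }))
  tr <- build_tree_from_cohort(ch, tiny_prices(), effect_measure = "ST")
  paths <- enumerate_paths(tr)
  expect_equal(nrow(paths), 2)
  expect_equal(paths$probability, c(1, 1))
  expect_error(build_tree_from_cohort(ch[1:2, ], tiny_prices()),
               "both strategies")
})

test_that("trees survive a JSON round-trip", {
  set.seed(13)
  tr <- random_ce_tree(3)
  f <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, f)
  back <- read_tree(f)
  expect_equal(rollback(back), rollback(tr), tolerance = 1e-12)
  expect_equal(enumerate_paths(back)$path, enumerate_paths(tr)$path)
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), f2)
  expect_error(read_tree(f2), "strategies")
})
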