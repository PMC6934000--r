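ref <- "preservative non-free"
comp <- "preservative-free"

test_that("ICERs from the published strategy table reproduce the printed ratios", {
  res <- ce_compare(reference_strategy_values(), ref, comp,
                    deltas = reference_deltas())
  icer <- function(m) res$icer[res$measure == m]
  # printed deltas 59.29 / 0.092 give 644.46, within printed rounding of 644.49
  expect_equal(icer("TMS"), 59.29 / 0.092, tolerance = 1e-12)
  expect_lt(abs(icer("TMS") - 644.49), 0.1)
  expect_equal(round(icer("ST"), 2), -27.94)
  expect_equal(res$quadrant[res$measure == "ST"], "NW")
  expect_equal(res$verdict[res$measure == "ST"], "dominated")
  expect_equal(res$quadrant[res$measure == "TMS"], "NE")
  expect_equal(res$verdict[res$measure == "TMS"], "highly_cost_effective")
  # without printed deltas, the strategy costs give the same cost delta
  res2 <- ce_compare(reference_strategy_values(), ref, comp)
  expect_true(all(abs(res2$delta_cost - 59.29) <= 0.01 + 1e-9))
  expect_equal(res2$delta_effect[res2$measure == "NIBUT"], 0.52,
               tolerance = 1e-12)
})

test_that("quadrants and degenerate comparisons follow the sign logic", {
  vals <- function(c_ref, e_ref, c_comp, e_comp) {
    tibble::tibble(strategy = c("R", "C"), cost = c(c_ref, c_comp),
                   effect = c(e_ref, e_comp))
  }
  r <- ce_compare(vals(100, 1, 80, 2), "R", "C")
  expect_equal(r$quadrant, "SE")
  expect_equal(r$verdict, "dominant")
  r <- ce_compare(vals(100, 1, 120, 0.5), "R", "C")
  expect_equal(r$quadrant, "NW")
  r <- ce_compare(vals(100, 1, 80, 0.5), "R", "C")
  expect_equal(r$quadrant, "SW")
  # zero effect delta: no division, ICER absent
  r <- ce_compare(vals(100, 1, 120, 1), "R", "C")
  expect_true(is.na(r$icer))
  expect_equal(r$verdict, "not_applicable")
})

test_that("swapping reference and comparator negates deltas, keeps the ICER", {
  set.seed(41)
  for (i in 1:30) {
    v <- tibble::tibble(strategy = c("R", "C"),
                        cost = runif(2, 0, 1000), effect = runif(2, -1, 2))
    a <- ce_compare(v, "R", "C")
    b <- ce_compare(v, "C", "R")
    expect_equal(b$delta_cost, -a$delta_cost)
    expect_equal(b$delta_effect, -a$delta_effect)
    if (!is.na(a$icer)) expect_equal(b$icer, a$icer, tolerance = 1e-12)
    mapping <- c(NE = "SW", SW = "NE", SE = "NW", NW = "SE")
    if (!is.na(a$quadrant)) expect_equal(b$quadrant, unname(mapping[a$quadrant]))
    # adding a constant cost to both strategies leaves the ICER unchanged
    v2 <- v; v2$cost <- v$cost + 500
    a2 <- ce_compare(v2, "R", "C")
    if (!is.na(a$icer)) expect_equal(a2$icer, a$icer, tolerance = 1e-9)
  }
})

test_that("WHO verdicts respect the GDP-multiple bands and their boundaries", {
  pol <- threshold_policy(gdp_per_capita = 15226)
  expect_equal(who_verdict(644.49, "NE", pol), "highly_cost_effective")
  expect_equal(who_verdict(15226, "NE", pol), "cost_effective")
  expect_equal(who_verdict(3 * 15226, "NE", pol), "cost_effective")
  expect_equal(who_verdict(3 * 15226 + 0.01, "NE", pol), "not_cost_effective")
  expect_equal(who_verdict(1e9, "SE", pol), "dominant")
  expect_equal(who_verdict(-5, "NW", pol), "dominated")
  # monotone in GDP for NE results: raising the threshold never worsens it
  rank <- c(not_cost_effective = 1, cost_effective = 2,
            highly_cost_effective = 3)
  gdps <- c(100, 1000, 15226, 1e6)
  for (icer in c(500, 20000, 50000)) {
    verdicts <- rank[vapply(gdps, function(g) {
      who_verdict(icer, "NE", threshold_policy(gdp_per_capita = g))
    }, character(1))]
    expect_true(all(diff(verdicts) >= 0))
  }
})

test_that("CE-plane coordinates carry the points and GDP threshold slopes", {
  res <- ce_compare(reference_strategy_values(), ref, comp,
                    deltas = reference_deltas())
  pl <- ce_plane(res)
  expect_setequal(pl$points$delta_effect, c(-2.122, 0.092, 0.52))
  expect_equal(unique(pl$points$delta_cost), 59.29)
  expect_equal(pl$thresholds$slope, c(15226, 45678))
  # degenerate comparison sits at the origin
  v0 <- tibble::tibble(strategy = c("R", "C"), cost = c(10, 10),
                       effect = c(1, 1))
  pl0 <- ce_plane(ce_compare(v0, "R", "C"))
  expect_equal(pl0$points$delta_effect, 0)
  expect_equal(pl0$points$delta_cost, 0)
})

test_that("tidy, glance and autoplot work on comparison tables", {
  res <- ce_compare(reference_strategy_values(), ref, comp,
                    deltas = reference_deltas())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(res)
  expect_equal(gl$n_comparisons, 3)
  expect_equal(gl$n_dominated, 1)
  expect_equal(gl$wtp_threshold, 45678)
  expect_s3_class(autoplot(res), "ggplot")
})
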