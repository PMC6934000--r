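# Shared fixtures: tiny hand-built cohorts, price lists and random trees.

tiny_prices <- function() {
  dplyr::bind_rows(
    drug_product("pgA", "latanoprost", "PG", TRUE, 10.00, 100),
    drug_product("pgB", "latanoprost", "PG", FALSE, 10.00, 100),
    drug_product("bbA", "timolol", "BB", FALSE, 5.00, 100),
    drug_product("atX", "hypromellose", "AT", TRUE, 2.00, 100)
  )
}

# n-eye hand-built cohort; defaults give one free monotherapy eye and one
# non-free combination eye, both with tears
tiny_cohort <- function() {
  dplyr::bind_rows(
    eye_record("t1", "p1", "left", "female", 60, "lt1y", 12, 2, 15, TRUE,
               "PG:latanoprost:2:pgA;AT:hypromellose:4:atX"),
    eye_record("t2", "p2", "right", "male", 70, "1to5y", 9, 4, 10, FALSE,
               "PG:latanoprost:2:pgB;BB:timolol:2:bbA")
  )
}

# random chance/terminal subtree; probabilities exactly sum to 1
random_subtree <- function(depth, max_depth, id = "n") {
  if (depth >= max_depth || runif(1) < 0.4) {
    return(terminal_node(paste0("leaf_", id), cost = runif(1, 0, 500),
                         effect = runif(1, -1, 2)))
  }
  k <- sample(2:3, 1)
  w <- runif(k, 0.05, 1)
  p <- w / sum(w)
  p[k] <- 1 - sum(p[-k])
  chance_node(paste0("chance_", id),
              lapply(seq_len(k), function(j) {
                branch(p[j], random_subtree(depth + 1, max_depth,
                                            paste0(id, j)))
              }))
}

random_ce_tree <- function(max_depth = 4) {
  decision_tree(
    strategy_node("S1", random_subtree(1, max_depth, "a")),
    strategy_node("S2", random_subtree(1, max_depth, "b"))
  )
}

# 4-leaf, two-strategy tree with simple round numbers, used by DSA tests
handbuilt_tree <- function() {
  decision_tree(
    strategy_node("ref", chance_node("mix", list(
      branch(0.6, terminal_node("r1", cost = 100, effect = 0.2)),
      branch(0.4, terminal_node("r2", cost = 300, effect = 0.5))
    ))),
    strategy_node("comp", chance_node("mix", list(
      branch(0.5, terminal_node("c1", cost = 200, effect = 0.4)),
      branch(0.5, terminal_node("c2", cost = 400, effect = 0.8))
    )))
  )
}

# ICER of a tree computed only through the path-enumeration oracle
oracle_icer <- function(tree, reference, comparator) {
  v <- path_enumeration_oracle(tree)
  r <- v[v$strategy == reference, ]
  m <- v[v$strategy == comparator, ]
  (m$expected_cost - r$expected_cost) / (m$expected_effect - r$expected_effect)
}
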