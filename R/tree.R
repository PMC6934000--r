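#' Decision-tree node constructors
#'
#' A two-strategy decision tree: the decision node holds one subtree per
#' strategy (here "preservative-free" vs "preservative non-free"); chance
#' nodes carry branches whose probabilities sum to 1; terminal nodes carry a
#' yearly cost payoff (BGN) and an effect payoff in the chosen effect unit
#' (good-control proportion for cohort-built trees).
#'
#' @param label Node label (character); strategy labels must be unique.
#' @param branches For `chance_node()`: a list of `(p, node)` pairs as
#'   produced by `branch()`.
#' @param cost,effect Terminal payoffs; `cost` must be non-negative.
#' @param root For `strategy_node()`: the chance or terminal node the
#'   strategy leads to.
#' @param strategies For `decision_tree()`: a list of `strategy_node()`s
#'   (at least two).
#' @return Nested lists of class `ce_tree` / internal node types.
#' @examples
#' tr <- decision_tree(
#'   strategy_node("A", terminal_node("a", cost = 100, effect = 1)),
#'   strategy_node("B", chance_node("mix", list(
#'     branch(0.5, terminal_node("b1", 100, 0)),
#'     branch(0.5, terminal_node("b2", 200, 1))
#'   )))
#' )
#' rollback(tr)
#' @export
decision_tree <- function(...) {
  strategies <- list(...)
  if (length(strategies) == 1 && !inherits(strategies[[1]], "strategy_node")) {
    strategies <- strategies[[1]]
  }
  if (length(strategies) < 2) abort("a decision tree needs at least 2 strategies")
  labs <- vapply(strategies, function(s) s$label, character(1))
  if (anyDuplicated(labs)) abort("strategy labels must be unique")
  structure(list(strategies = strategies), class = "ce_tree")
}

#' @rdname decision_tree
#' @export
strategy_node <- function(label, root) {
  structure(list(type = "strategy", label = label, root = root),
            class = "strategy_node")
}

#' @rdname decision_tree
#' @param p Branch probability in `[0, 1]`.
#' @param node Child node.
#' @export
branch <- function(p, node) list(p = p, node = node)

#' @rdname decision_tree
#' @export
chance_node <- function(label, branches) {
  structure(list(type = "chance", label = label, branches = branches),
            class = "ce_node")
}

#' @rdname decision_tree
#' @export
terminal_node <- function(label, cost, effect) {
  structure(list(type = "terminal", label = label, cost = cost,
                 effect = effect), class = "ce_node")
}

#' @export
print.ce_tree <- function(x, ...) {
  cat(sprintf("<ce_tree> %d strategies, %d leaves\n",
              length(x$strategies), nrow(enumerate_paths(x))))
  for (s in x$strategies) cat("  strategy:", s$label, "\n")
  invisible(x)
}

#' Validate a decision tree
#'
#' Structural checks returned as findings, not errors: every chance node's
#' branch probabilities must sum to 1 within `tol` and lie in `[0, 1]`, and
#' every terminal cost must be non-negative.
#'
#' @param tree A `ce_tree`.
#' @param tol Probability-sum tolerance (default 1e-9).
#' @return A character vector of violations; empty when the tree is valid.
#' @examples
#' validate_tree(decision_tree(
#'   strategy_node("A", terminal_node("a", 1, 1)),
#'   strategy_node("B", terminal_node("b", 2, 2))
#' ))
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  if (!inherits(tree, "ce_tree")) abort("`tree` must be a ce_tree")
  violations <- character()
  walk <- function(node, path) {
    if (node$type == "terminal") {
      if (!is.finite(node$cost) || node$cost < 0) {
        violations <<- c(violations,
                         sprintf("terminal `%s`: negative or missing cost", path))
      }
      if (!is.finite(node$effect)) {
        violations <<- c(violations,
                         sprintf("terminal `%s`: missing effect", path))
      }
    } else {
      ps <- vapply(node$branches, function(b) b$p, numeric(1))
      if (any(ps < -tol | ps > 1 + tol)) {
        violations <<- c(violations,
                         sprintf("chance `%s`: branch probability outside [0, 1]", path))
      }
      if (abs(sum(ps) - 1) > tol) {
        violations <<- c(violations,
                         sprintf("chance `%s`: probabilities sum to %.12g, not 1",
                                 path, sum(ps)))
      }
      for (b in node$branches) {
        walk(b$node, paste(path, b$node$label, sep = "/"))
      }
    }
  }
  for (s in tree$strategies) walk(s$root, paste(s$label, s$root$label, sep = "/"))
  violations
}

#' Expected cost and effect by recursive roll-back
#'
#' Rolls the tree back from the leaves: a terminal contributes its payoffs,
#' a chance node the probability-weighted sum of its children. The result is
#' identical (to 1e-9) to the independent [path_enumeration_oracle()].
#'
#' @param tree A valid `ce_tree`.
#' @return A tibble with one row per strategy: `strategy`, `expected_cost`
#'   (BGN), `expected_effect`.
#' @examples
#' rollback(reference_tree())
#' @export
rollback <- function(tree) {
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("invalid tree:\n", paste("-", v, collapse = "\n")))
  }
  value <- function(node) {
    if (node$type == "terminal") return(c(cost = node$cost, effect = node$effect))
    vals <- lapply(node$branches, function(b) b$p * value(b$node))
    Reduce(`+`, vals)
  }
  purrr::map_dfr(tree$strategies, function(s) {
    ev <- value(s$root)
    tibble::tibble(strategy = s$label, expected_cost = unname(ev["cost"]),
                   expected_effect = unname(ev["effect"]))
  })
}

#' Enumerate every root-to-leaf path of a tree
#'
#' @param tree A `ce_tree`.
#' @return A tibble with `strategy`, `path` (slash-joined labels),
#'   `probability` (product of branch probabilities), `cost`, `effect`.
#' @examples
#' enumerate_paths(reference_tree())
#' @export
enumerate_paths <- function(tree) {
  if (!inherits(tree, "ce_tree")) abort("`tree` must be a ce_tree")
  out <- list()
  walk <- function(node, strategy, path, prob) {
    if (node$type == "terminal") {
      out[[length(out) + 1]] <<- tibble::tibble(
        strategy = strategy, path = path, probability = prob,
        cost = node$cost, effect = node$effect)
    } else {
      for (b in node$branches) {
        walk(b$node, strategy, paste(path, b$node$label, sep = "/"), prob * b$p)
      }
    }
  }
  for (s in tree$strategies) {
    walk(s$root, s$label, paste(s$label, s$root$label, sep = "/"), 1)
  }
  dplyr::bind_rows(out)
}

#' Path-enumeration oracle for expected values
#'
#' Independent check on [rollback()]: enumerates all root-to-leaf paths,
#' multiplies branch probabilities along each, and sums payoff times path
#' probability per strategy.
#'
#' @inheritParams rollback
#' @return Same shape as [rollback()].
#' @export
path_enumeration_oracle <- function(tree) {
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("invalid tree:\n", paste("-", v, collapse = "\n")))
  }
  enumerate_paths(tree) |>
    dplyr::group_by(strategy = .data$strategy) |>
    dplyr::summarise(
      expected_cost = sum(.data$probability * .data$cost),
      expected_effect = sum(.data$probability * .data$effect),
      .groups = "drop"
    ) |>
    # preserve strategy declaration order rather than alphabetical
    dplyr::arrange(match(.data$strategy,
                         vapply(tree$strategies, function(s) s$label,
                                character(1))))
}

#' Estimate a branch probability from cohort counts
#'
#' Plain maximum-likelihood proportion `n_event / n_total`, with no
#' smoothing or continuity correction.
#'
#' @param n_event Number of eyes with the event.
#' @param n_total Total eyes (positive).
#' @return The exact proportion.
#' @examples
#' estimate_probability(20, 64)  # 0.3125
#' @export
estimate_probability <- function(n_event, n_total) {
  if (any(n_total == 0)) abort("undefined probability: n_total is 0")
  if (any(n_event < 0) || any(n_event > n_total)) {
    abort("`n_event` must lie in [0, n_total]")
  }
  n_event / n_total
}

#' Build the two-strategy tree from a cohort
#'
#' Strategy arms are the eye-level preservative flag. Within each arm the
#' first chance level is mono vs combination therapy; the second level is
#' the therapeutic class (monotherapy) or the combination composition. Each
#' terminal's cost is the arithmetic mean of its member eyes' total yearly
#' cost (glaucoma + dry eye), which makes roll-back reproduce the
#' cohort-weighted average cost; its effect is the proportion of member
#' eyes with good control on `effect_measure`. Strata with no eyes simply
#' never appear (probabilities are exact cohort proportions, so siblings
#' always sum to 1).
#'
#' @param cohort A valid cohort tibble with both strategies represented.
#' @param prices A price-list tibble resolving every therapy line.
#' @param thresholds A [control_thresholds()] object.
#' @param effect_measure `"ST"`, `"TMS"` or `"NIBUT"`.
#' @param strategy_labels Names for the two arms, `c(free, non_free)`.
#' @return A `ce_tree`.
#' @examples
#' study <- generate_cohort(default_config())
#' tr <- build_tree_from_cohort(study$cohort, study$prices,
#'                              effect_measure = "TMS")
#' rollback(tr)
#' @export
build_tree_from_cohort <- function(cohort, prices,
                                   thresholds = control_thresholds(),
                                   effect_measure = c("TMS", "NIBUT", "ST"),
                                   strategy_labels = c("preservative-free",
                                                       "preservative non-free")) {
  effect_measure <- match.arg(effect_measure)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) abort("empty cohort")
  validate_cohort(cohort, mode = "lenient")
  if (length(unique(cohort$preservative_free)) < 2) {
    abort("both strategies (preservative-free and non-free) must be represented")
  }
  good_col <- c(ST = "st_good", TMS = "tms_good", NIBUT = "nibut_good")[effect_measure]
  eyes <- classify_control(cohort, thresholds) |>
    dplyr::left_join(eye_yearly_cost(cohort, prices) |>
                       dplyr::select("eye_id", "glaucoma_cost", "dry_eye_cost"),
                     by = "eye_id") |>
    dplyr::mutate(
      total_cost = .data$glaucoma_cost + .data$dry_eye_cost,
      good = .data[[good_col]],
      therapy_type = ifelse(n_glaucoma_lines(cohort) >= 2,
                            "combination", "monotherapy")
    )
  glines <- therapy_lines(cohort) |> dplyr::filter(.data$is_glaucoma)
  eyes$leaf <- vapply(eyes$eye_id, function(id) {
    combo_label(glines$drug_class[glines$eye_id == id])
  }, character(1))

  make_leaf <- function(sub, label) {
    terminal_node(label, cost = mean(sub$total_cost),
                  effect = mean(sub$good))
  }
  make_type_node <- function(sub, type_label) {
    leaves <- split(sub, sub$leaf)
    if (length(leaves) == 1) {
      return(make_leaf(sub, names(leaves)[1]))
    }
    chance_node(type_label, lapply(names(leaves), function(lab) {
      branch(estimate_probability(nrow(leaves[[lab]]), nrow(sub)),
             make_leaf(leaves[[lab]], lab))
    }))
  }
  make_arm <- function(sub, label) {
    types <- split(sub, sub$therapy_type)
    if (length(types) == 1) {
      node <- make_type_node(types[[1]], names(types)[1])
    } else {
      node <- chance_node("therapy mix", lapply(names(types), function(tp) {
        branch(estimate_probability(nrow(types[[tp]]), nrow(sub)),
               make_type_node(types[[tp]], tp))
      }))
    }
    strategy_node(label, node)
  }
  decision_tree(
    make_arm(eyes[eyes$preservative_free, ], strategy_labels[1]),
    make_arm(eyes[!eyes$preservative_free, ], strategy_labels[2])
  )
}

#' Read / write a decision tree as JSON
#'
#' Nested JSON with explicit node `type` tags (`strategy`, `chance`,
#' `terminal`), branch probabilities and terminal payoffs; validated on
#' load.
#'
#' @param tree A `ce_tree`.
#' @param path JSON file path.
#' @return `write_tree()`: `path` invisibly; `read_tree()`: a validated
#'   `ce_tree`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_tree(reference_tree(), f)
#' validate_tree(read_tree(f))
#' @export
write_tree <- function(tree, path) {
  if (!inherits(tree, "ce_tree")) abort("`tree` must be a ce_tree")
  strip <- function(node) {
    if (node$type == "terminal") {
      list(type = "terminal", label = node$label, cost = node$cost,
           effect = node$effect)
    } else {
      list(type = "chance", label = node$label,
           branches = lapply(node$branches, function(b) {
             list(p = b$p, node = strip(b$node))
           }))
    }
  }
  payload <- list(strategies = lapply(tree$strategies, function(s) {
    list(type = "strategy", label = s$label, root = strip(s$root))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$strategies)) abort("tree JSON: missing `strategies`")
  rebuild <- function(node) {
    if (identical(node$type, "terminal")) {
      terminal_node(node$label, as.numeric(node$cost), as.numeric(node$effect))
    } else if (identical(node$type, "chance")) {
      chance_node(node$label, lapply(node$branches, function(b) {
        branch(as.numeric(b$p), rebuild(b$node))
      }))
    } else {
      abort(sprintf("tree JSON: unknown node type `%s`",
                    node$type %||% "<missing>"))
    }
  }
  tree <- decision_tree(lapply(payload$strategies, function(s) {
    strategy_node(s$label, rebuild(s$root))
  }))
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("tree JSON failed validation:\n", paste("-", v, collapse = "\n")))
  }
  tree
}
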