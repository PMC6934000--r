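#' Comparison specification for sensitivity analyses
#'
#' Bundles the reference and comparator strategy labels with the
#' willingness-to-pay policy so DSA functions can recompute the ICER after
#' each perturbation.
#'
#' @param reference,comparator Strategy labels as in [ce_compare()].
#' @param policy A [threshold_policy()].
#' @return A list of class `comparison_spec`.
#' @examples
#' comparison_spec("preservative non-free", "preservative-free")
#' @export
comparison_spec <- function(reference, comparator,
                            policy = threshold_policy()) {
  structure(list(reference = reference, comparator = comparator,
                 policy = policy), class = "comparison_spec")
}

#' List the perturbable parameters of a tree
#'
#' Parameter ids are slash-joined node paths with an `@field` suffix:
#' `strategy/.../leaf@cost`, `.../leaf@effect`, or `.../node@prob` for the
#' probability of the branch leading into a node. By default only leaf
#' costs and effects are listed (the quantities varied in the published
#' analysis); set `include_probabilities = TRUE` to add branch
#' probabilities.
#'
#' @param tree A `ce_tree`.
#' @param include_probabilities Also list branch probabilities.
#' @return A character vector of parameter ids.
#' @examples
#' tree_parameters(reference_tree())
#' @export
tree_parameters <- function(tree, include_probabilities = FALSE) {
  if (!inherits(tree, "ce_tree")) abort("`tree` must be a ce_tree")
  out <- character()
  walk <- function(node, path) {
    if (node$type == "terminal") {
      out <<- c(out, paste0(path, "@cost"), paste0(path, "@effect"))
    } else {
      for (b in node$branches) {
        child_path <- paste(path, b$node$label, sep = "/")
        if (include_probabilities) out <<- c(out, paste0(child_path, "@prob"))
        walk(b$node, child_path)
      }
    }
  }
  for (s in tree$strategies) walk(s$root, paste(s$label, s$root$label, sep = "/"))
  out
}

# Apply `f` to the field addressed by `parameter_id`; returns the modified
# tree (the input is never mutated). Probabilities are clamped to [0, 1] and
# siblings renormalised proportionally so the chance node still sums to 1.
perturb_parameter <- function(tree, parameter_id, delta) {
  parts <- strsplit(parameter_id, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !(parts[2] %in% c("cost", "effect", "prob"))) {
    abort(sprintf("cannot parse parameter id `%s` (expected path@cost|effect|prob)",
                  parameter_id))
  }
  field <- parts[2]
  segs <- strsplit(parts[1], "/", fixed = TRUE)[[1]]
  if (length(segs) < 2) abort(sprintf("parameter path `%s` is too short", parts[1]))
  slab <- segs[1]
  si <- which(vapply(tree$strategies, function(s) s$label, character(1)) == slab)
  if (length(si) != 1) {
    abort(sprintf("parameter `%s`: strategy `%s` not found", parameter_id, slab))
  }
  strat <- tree$strategies[[si]]
  if (strat$root$label != segs[2]) {
    abort(sprintf("parameter `%s`: node `%s` not found under strategy `%s`",
                  parameter_id, segs[2], slab))
  }

  descend <- function(node, rest) {
    if (length(rest) == 0) {
      if (field == "prob") {
        abort(sprintf("parameter `%s`: @prob must address a branch child, not a root",
                      parameter_id))
      }
      if (node$type != "terminal") {
        abort(sprintf("parameter `%s`: `%s` is not a terminal node",
                      parameter_id, node$label))
      }
      node[[field]] <- node[[field]] * (1 + delta)
      if (field == "cost" && node$cost < 0) node$cost <- 0
      return(node)
    }
    if (node$type != "chance") {
      abort(sprintf("parameter `%s`: path continues past terminal `%s`",
                    parameter_id, node$label))
    }
    labs <- vapply(node$branches, function(b) b$node$label, character(1))
    bi <- which(labs == rest[1])
    if (length(bi) != 1) {
      abort(sprintf("parameter `%s`: node `%s` not found under `%s`",
                    parameter_id, rest[1], node$label))
    }
    if (length(rest) == 1 && field == "prob") {
      p_old <- node$branches[[bi]]$p
      p_new <- min(1, max(0, p_old * (1 + delta)))
      others <- setdiff(seq_along(node$branches), bi)
      s_others <- sum(vapply(node$branches[others], function(b) b$p, numeric(1)))
      if (s_others > 0) {
        scale <- (1 - p_new) / s_others
        for (j in others) node$branches[[j]]$p <- node$branches[[j]]$p * scale
      } else if (p_new != 1) {
        warn(sprintf("parameter `%s`: no sibling mass to renormalise; probability kept at 1",
                     parameter_id))
        p_new <- 1
      }
      node$branches[[bi]]$p <- p_new
      return(node)
    }
    node$branches[[bi]]$node <- descend(node$branches[[bi]]$node, rest[-1])
    node
  }
  strat$root <- descend(strat$root, segs[-c(1, 2)])
  tree$strategies[[si]] <- strat
  tree
}

dsa_icer <- function(tree, spec) {
  vals <- rollback(tree)
  res <- ce_compare(vals, spec$reference, spec$comparator, policy = spec$policy)
  res$icer[1]
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-evaluates the strategy values and ICER with the addressed parameter
#' set to its low and high perturbed values (all other parameters at base),
#' by default -30% and +30% of the base value. The base tree is never
#' mutated. An endpoint where the perturbed effect delta is zero is flagged
#' undefined (`NA` ICER).
#'
#' @param tree A valid `ce_tree`.
#' @param spec A [comparison_spec()].
#' @param parameter_id A parameter id from [tree_parameters()].
#' @param relative_range Length-2 relative perturbation, default
#'   `c(-0.3, 0.3)`.
#' @return A one-row tibble: `parameter_id`, `base_icer`, `icer_low`,
#'   `icer_high`, `width` (`|icer_high - icer_low|`), `undefined`.
#' @examples
#' tr <- reference_tree()
#' spec <- comparison_spec("preservative non-free", "preservative-free")
#' one_way_dsa(tr, spec, tree_parameters(tr)[1])
#' @export
one_way_dsa <- function(tree, spec, parameter_id,
                        relative_range = c(-0.3, 0.3)) {
  stopifnot(inherits(spec, "comparison_spec"), length(relative_range) == 2)
  base <- dsa_icer(tree, spec)
  if (is.na(base)) abort("base ICER is undefined (zero effect delta)")
  at <- function(delta) dsa_icer(perturb_parameter(tree, parameter_id, delta), spec)
  lo <- at(relative_range[1])
  hi <- at(relative_range[2])
  tibble::tibble(
    parameter_id = parameter_id, base_icer = base,
    icer_low = lo, icer_high = hi,
    width = abs(hi - lo),
    undefined = is.na(lo) | is.na(hi)
  )
}

#' Tornado table: one-way DSA over a set of parameters
#'
#' Runs [one_way_dsa()] for every parameter and orders the entries by
#' descending width (the tornado ordering), breaking ties by parameter id.
#' By default all leaf costs and effects are varied; branch probabilities
#' can be added explicitly. Duplicated parameter ids produce identical
#' entries and a warning.
#'
#' @inheritParams one_way_dsa
#' @param parameters Character vector of parameter ids; default
#'   `tree_parameters(tree)`.
#' @return A tibble of class `tornado_tbl`, sorted as rendered.
#' @examples
#' tr <- reference_tree()
#' spec <- comparison_spec("preservative non-free", "preservative-free")
#' tornado(tr, spec)
#' @export
tornado <- function(tree, spec, parameters = NULL,
                    relative_range = c(-0.3, 0.3)) {
  parameters <- parameters %||% tree_parameters(tree)
  if (length(parameters) < 1) abort("need at least one parameter")
  if (anyDuplicated(parameters)) {
    warn(sprintf("duplicated parameter id `%s` in tornado set",
                 parameters[anyDuplicated(parameters)]))
  }
  out <- purrr::map_dfr(parameters, function(p) {
    one_way_dsa(tree, spec, p, relative_range = relative_range)
  }) |>
    dplyr::arrange(dplyr::desc(.data$width), .data$parameter_id)
  structure(out, class = c("tornado_tbl", class(out)))
}

#' Scan a perturbation grid for an ICER sign flip
#'
#' Evaluates the ICER at each grid point for one parameter, in order of
#' increasing perturbation magnitude, and reports the smallest perturbation
#' at which the ICER's sign differs from the base sign. Grid points with an
#' undefined ICER are skipped with a warning. The default grid is 61 evenly
#' spaced points over \[-30%, +30%\] (1% steps).
#'
#' @inheritParams one_way_dsa
#' @param grid Numeric vector of relative perturbations.
#' @return A tibble with zero rows when no flip occurs, else one row:
#'   `parameter_id`, `flip_at`, `icer_at_flip`, `base_icer`.
#' @examples
#' tr <- reference_tree()
#' spec <- comparison_spec("preservative non-free", "preservative-free")
#' sign_flip_scan(tr, spec, tree_parameters(tr)[2])
#' @export
sign_flip_scan <- function(tree, spec, parameter_id,
                           grid = seq(-0.3, 0.3, length.out = 61)) {
  base <- dsa_icer(tree, spec)
  if (is.na(base)) abort("base ICER is undefined (zero effect delta)")
  grid <- grid[order(abs(grid), grid)]
  for (delta in grid) {
    if (delta == 0) next
    v <- dsa_icer(perturb_parameter(tree, parameter_id, delta), spec)
    if (is.na(v)) {
      warn(sprintf("ICER undefined at perturbation %+.0f%%; point skipped",
                   100 * delta))
      next
    }
    if (sign(v) != sign(base)) {
      return(tibble::tibble(parameter_id = parameter_id, flip_at = delta,
                            icer_at_flip = v, base_icer = base))
    }
  }
  tibble::tibble(parameter_id = character(), flip_at = double(),
                 icer_at_flip = double(), base_icer = double())
}

#' Tornado diagram plot
#'
#' @param object A `tornado_tbl` from [tornado()].
#' @param ... Unused.
#' @return A ggplot of horizontal bars spanning each parameter's low/high
#'   ICER around the base-case ICER, widest on top.
#' @method autoplot tornado_tbl
#' @export
autoplot.tornado_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$undefined) |>
    dplyr::mutate(parameter_id = factor(.data$parameter_id,
                                        levels = rev(.data$parameter_id)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter_id),
                          linewidth = 4, colour = "#74a9cf") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$base_icer),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (BGN per effect unit)", y = NULL,
                  title = "Tornado diagram (one-way DSA, ±30%)") +
    ggplot2::theme_minimal()
}
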