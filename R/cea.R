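#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes, per effect measure, the cost and effect deltas of the
#' comparator strategy minus the reference strategy, the ICER
#' (`delta_cost / delta_effect`, undefined when the effect delta is zero),
#' the cost-effectiveness-plane quadrant, and the WHO GDP-multiple verdict.
#' The reference is current practice (preservative-containing therapy) and
#' the comparator the preservative-free strategy, so a positive
#' `delta_cost` means the comparator costs more.
#'
#' Quadrants: `NE` costlier and more effective (ICER interpretable as a
#' price per unit of effect); `SE` cheaper and more effective (comparator
#' dominant); `NW` costlier and less effective (comparator dominated);
#' `SW` cheaper and less effective. In SE/NW the ICER is still reported but
#' is not interpretable as a price.
#'
#' `deltas` supports reproduction from published strategy-level tables: when
#' a tibble of printed `delta_cost`/`delta_effect` values (per measure) is
#' supplied, ICERs are computed from those printed deltas rather than from
#' differences of the (rounded) printed strategy values.
#'
#' @param values A tibble of strategy values: columns `strategy`,
#'   `cost`/`expected_cost`, `effect`/`expected_effect` and optionally
#'   `measure` (one comparison is made per measure).
#' @param reference,comparator Strategy labels present in `values`.
#' @param policy A [threshold_policy()].
#' @param deltas Optional tibble with `delta_cost`, `delta_effect` (and
#'   `measure` when `values` has one) taken as the deltas instead of the
#'   computed differences.
#' @return A tibble of class `cea_tbl`, one row per measure, with the
#'   policy attached as attribute `policy`.
#' @examples
#' ce_compare(reference_strategy_values(),
#'            reference = "preservative non-free",
#'            comparator = "preservative-free",
#'            deltas = reference_deltas())
#' @export
ce_compare <- function(values, reference, comparator,
                       policy = threshold_policy(), deltas = NULL) {
  stopifnot(is.data.frame(values))
  names(values)[names(values) == "expected_cost"] <- "cost"
  names(values)[names(values) == "expected_effect"] <- "effect"
  need <- c("strategy", "cost", "effect")
  if (!all(need %in% names(values))) {
    abort("`values` needs columns strategy, cost|expected_cost, effect|expected_effect")
  }
  has_measure <- "measure" %in% names(values)
  if (!has_measure) values$measure <- "effect"
  for (s in c(reference, comparator)) {
    if (!s %in% values$strategy) abort(sprintf("strategy `%s` not in `values`", s))
  }
  if (!is.null(deltas) && !has_measure) deltas$measure <- "effect"

  rows <- values |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_map(function(g, key) {
      r <- g[g$strategy == reference, ]
      m <- g[g$strategy == comparator, ]
      if (nrow(r) != 1 || nrow(m) != 1) {
        abort(sprintf("measure `%s`: need exactly one row per strategy",
                      key$measure))
      }
      dC <- m$cost - r$cost
      dE <- m$effect - r$effect
      if (!is.null(deltas)) {
        d <- deltas[deltas$measure == key$measure, ]
        if (nrow(d) == 1) {
          if ("delta_cost" %in% names(d) && !is.na(d$delta_cost)) dC <- d$delta_cost
          if ("delta_effect" %in% names(d) && !is.na(d$delta_effect)) dE <- d$delta_effect
        }
      }
      tibble::tibble(
        measure = key$measure, reference = reference, comparator = comparator,
        cost_ref = r$cost, effect_ref = r$effect,
        cost_comp = m$cost, effect_comp = m$effect,
        delta_cost = dC, delta_effect = dE,
        icer = if (dE == 0) NA_real_ else dC / dE,
        quadrant = ce_quadrant(dC, dE)
      )
    }) |>
    dplyr::bind_rows()
  rows$verdict <- who_verdict(rows$icer, rows$quadrant, policy)
  if (!has_measure) rows$measure <- NULL
  structure(rows, class = c("cea_tbl", class(rows)), policy = policy)
}

#' Cost-effectiveness-plane quadrant from the sign of the deltas
#'
#' @param delta_cost,delta_effect Comparator-minus-reference deltas.
#' @return `"NE"`, `"SE"`, `"NW"`, `"SW"`, or `NA` when the effect delta is
#'   zero (the comparison degenerates onto the cost axis).
#' @examples
#' ce_quadrant(59.29, -2.122)  # "NW"
#' @export
ce_quadrant <- function(delta_cost, delta_effect) {
  dplyr::case_when(
    delta_effect == 0 ~ NA_character_,
    delta_effect > 0 & delta_cost > 0 ~ "NE",
    delta_effect > 0 & delta_cost <= 0 ~ "SE",
    delta_effect < 0 & delta_cost > 0 ~ "NW",
    TRUE ~ "SW"
  )
}

#' WHO GDP-multiple verdict for an ICER
#'
#' In the NE quadrant (comparator costlier and more effective) the ICER is
#' graded against GDP per capita: below `multiplier_low` x GDP it is highly
#' cost-effective, up to and including `multiplier_high` x GDP it is
#' cost-effective (closed upper bound), and above that not cost-effective.
#' SE means the comparator dominates; NW means it is dominated. In SW
#' (cheaper, less effective) the threshold is applied to the reversed
#' comparison: forgoing effect is acceptable iff the savings per unit of
#' effect lost exceed `multiplier_high` x GDP.
#'
#' @param icer ICER in BGN per effect unit (may be `NA`).
#' @param quadrant As from [ce_quadrant()].
#' @param policy A [threshold_policy()].
#' @return Character verdicts: `highly_cost_effective`, `cost_effective`,
#'   `not_cost_effective`, `dominant`, `dominated` or `not_applicable`.
#' @examples
#' who_verdict(644.49, "NE")  # highly_cost_effective
#' @export
who_verdict <- function(icer, quadrant, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  low <- policy$multiplier_low * policy$gdp_per_capita
  high <- policy$multiplier_high * policy$gdp_per_capita
  dplyr::case_when(
    is.na(quadrant) ~ "not_applicable",
    quadrant == "SE" ~ "dominant",
    quadrant == "NW" ~ "dominated",
    quadrant == "SW" & icer > high ~ "cost_effective",
    quadrant == "SW" ~ "not_cost_effective",
    icer < low ~ "highly_cost_effective",
    icer <= high ~ "cost_effective",
    TRUE ~ "not_cost_effective"
  )
}

#' Cost-effectiveness-plane coordinates
#'
#' Plot-ready export of each comparison as a `(delta_effect, delta_cost)`
#' point, together with the willingness-to-pay threshold lines through the
#' origin (slopes 1x and 3x GDP per capita in BGN per effect unit). No
#' rendering; see [autoplot.cea_tbl()] for a ggplot.
#'
#' @param results A `cea_tbl` from [ce_compare()].
#' @param policy A [threshold_policy()]; defaults to the one attached to
#'   `results`.
#' @return A list with `points` (tibble `label`, `delta_effect`,
#'   `delta_cost`) and `thresholds` (tibble `name`, `slope`).
#' @examples
#' res <- ce_compare(reference_strategy_values(),
#'                   "preservative non-free", "preservative-free")
#' ce_plane(res)
#' @export
ce_plane <- function(results, policy = NULL) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  policy <- policy %||% attr(results, "policy") %||% threshold_policy()
  label <- if ("measure" %in% names(results)) results$measure else results$comparator
  list(
    points = tibble::tibble(label = label,
                            delta_effect = results$delta_effect,
                            delta_cost = results$delta_cost),
    thresholds = tibble::tibble(
      name = c("1x GDP", sprintf("%gx GDP", policy$multiplier_high)),
      slope = c(policy$multiplier_low, policy$multiplier_high) *
        policy$gdp_per_capita
    )
  )
}

#' Published strategy-level values for the 64-eye Bulgarian POAG+DE cohort
#'
#' Strategy-level expected yearly costs (BGN) and effects reported for the
#' preservative-containing (reference) and preservative-free (comparator)
#' strategies under each of the three tear-film effect measures, together
#' with the printed deltas ([reference_deltas()]). These are reproduction
#' inputs: the printed per-strategy values are rounded, so ICER reproduction
#' uses the printed deltas. Note the published NIBUT ICER cell (93.48) is
#' inconsistent with its own printed deltas (59.29 / 0.52 = 114.02), as is
#' the abstract's 744/131 pair; this package reports ratios computed from
#' the printed deltas and leaves those cells unreproduced.
#'
#' @return `reference_strategy_values()`: tibble `measure`, `strategy`,
#'   `cost`, `effect`. `reference_deltas()`: tibble `measure`, `delta_cost`,
#'   `delta_effect`.
#' @examples
#' reference_strategy_values()
#' @export
reference_strategy_values <- function() {
  tibble::tibble(
    measure = rep(c("ST", "TMS", "NIBUT"), each = 2),
    strategy = rep(c("preservative non-free", "preservative-free"), 3),
    cost = rep(c(444.50, 503.80), 3),
    effect = c(3.52, 1.40, 3.51, 3.62, 0.48, 1.00)
  )
}

#' @rdname reference_strategy_values
#' @export
reference_deltas <- function() {
  tibble::tibble(
    measure = c("ST", "TMS", "NIBUT"),
    delta_cost = rep(59.29, 3),
    delta_effect = c(-2.122, 0.092, 0.52)
  )
}

#' @export
print.cea_tbl <- function(x, ...) {
  cat("<cea_tbl> incremental cost-effectiveness comparisons\n")
  print(tibble::as_tibble(x), ...)
  pol <- attr(x, "policy")
  if (!is.null(pol)) {
    cat(sprintf("WTP threshold: %gx GDP = %s BGN per effect unit\n",
                pol$multiplier_high,
                format(pol$multiplier_high * pol$gdp_per_capita, big.mark = ",")))
  }
  invisible(x)
}

#' @rdname ce_compare
#' @param x A `cea_tbl`.
#' @param ... Unused.
#' @method tidy cea_tbl
#' @export
tidy.cea_tbl <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname ce_compare
#' @method glance cea_tbl
#' @export
glance.cea_tbl <- function(x, ...) {
  pol <- attr(x, "policy") %||% threshold_policy()
  tibble::tibble(
    n_comparisons = nrow(x),
    n_dominant = sum(x$verdict == "dominant"),
    n_dominated = sum(x$verdict == "dominated"),
    n_cost_effective = sum(x$verdict %in%
                             c("highly_cost_effective", "cost_effective")),
    wtp_threshold = pol$multiplier_high * pol$gdp_per_capita
  )
}

#' Cost-effectiveness plane plot
#'
#' @param object A `cea_tbl` from [ce_compare()].
#' @param ... Unused.
#' @return A ggplot: one point per comparison on the
#'   (effect delta, cost delta) plane with the 1x and 3x GDP
#'   willingness-to-pay rays.
#' @method autoplot cea_tbl
#' @export
autoplot.cea_tbl <- function(object, ...) {
  pl <- ce_plane(object)
  ggplot2::ggplot(pl$points,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(data = pl$thresholds,
                         ggplot2::aes(slope = .data$slope, intercept = 0,
                                      linetype = .data$name),
                         colour = "grey40") +
    ggplot2::geom_point(size = 2.5, colour = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "incremental effect (good-control units)",
                  y = "incremental cost (BGN/year)",
                  linetype = "WTP threshold",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
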