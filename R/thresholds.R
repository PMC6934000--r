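#' Disease-control thresholds for the three tear-film tests
#'
#' Dichotomisation cut-offs for the Schirmer test (ST, mm of wetted strip),
#' the total meiboscore (TMS, 0--6 meibomian-gland loss score summed over
#' both eyelids) and the non-invasive tear break-up time (NIBUT, seconds).
#' Good control means ST *above* its threshold, TMS *below* its threshold
#' (low gland loss is good) and NIBUT *above* its threshold.
#'
#' Values sitting exactly on a threshold are classified as poor control by
#' default: the clinical definitions only speak of "above"/"below", so the
#' conservative convention is adopted; set `boundary = "good"` to include
#' boundary values on the good side.
#'
#' @param st_threshold_mm Schirmer-test cut-off in mm (default 10).
#' @param tms_threshold Total-meiboscore cut-off (default 3).
#' @param nibut_threshold_s NIBUT cut-off in seconds (default 14).
#' @param boundary How to classify values exactly at a threshold:
#'   `"poor"` (default, strict inequalities) or `"good"`.
#' @return A list of class `control_thresholds`.
#' @examples
#' control_thresholds()
#' control_thresholds(st_threshold_mm = 12)
#' @export
control_thresholds <- function(st_threshold_mm = 10, tms_threshold = 3,
                               nibut_threshold_s = 14,
                               boundary = c("poor", "good")) {
  boundary <- match.arg(boundary)
  for (nm in c("st_threshold_mm", "tms_threshold", "nibut_threshold_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number", nm))
    }
  }
  structure(
    list(st_threshold_mm = st_threshold_mm, tms_threshold = tms_threshold,
         nibut_threshold_s = nibut_threshold_s, boundary = boundary),
    class = "control_thresholds"
  )
}

#' @export
print.control_thresholds <- function(x, ...) {
  cat("<control_thresholds>\n")
  cat(sprintf("  ST  good: > %g mm\n", x$st_threshold_mm))
  cat(sprintf("  TMS good: < %g\n", x$tms_threshold))
  cat(sprintf("  NIBUT good: > %g s\n", x$nibut_threshold_s))
  cat(sprintf("  boundary values: %s\n", x$boundary))
  invisible(x)
}

#' Willingness-to-pay threshold policy (WHO GDP multiples)
#'
#' The WHO convention grades an incremental cost-effectiveness ratio (ICER)
#' against multiples of GDP per capita: below 1x GDP per unit of effect is
#' highly cost-effective, between 1x and 3x is cost-effective, above 3x is
#' not cost-effective. The default GDP per capita is Bulgaria's 15,226 BGN.
#'
#' @param gdp_per_capita GDP per capita in BGN (default 15226).
#' @param multiplier_low Lower multiple (default 1).
#' @param multiplier_high Upper multiple (default 3).
#' @return A list of class `threshold_policy`.
#' @examples
#' threshold_policy()
#' @export
threshold_policy <- function(gdp_per_capita = 15226, multiplier_low = 1,
                             multiplier_high = 3) {
  if (!is.numeric(gdp_per_capita) || length(gdp_per_capita) != 1 ||
      gdp_per_capita <= 0) {
    abort("`gdp_per_capita` must be a single positive number")
  }
  if (multiplier_high < multiplier_low) {
    abort("`multiplier_high` must be >= `multiplier_low`")
  }
  structure(
    list(gdp_per_capita = gdp_per_capita, multiplier_low = multiplier_low,
         multiplier_high = multiplier_high),
    class = "threshold_policy"
  )
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("<threshold_policy>\n")
  cat(sprintf("  GDP per capita: %s BGN\n", format(x$gdp_per_capita, big.mark = ",")))
  cat(sprintf("  cost-effective band: %g-%gx GDP (%s-%s BGN/unit effect)\n",
              x$multiplier_low, x$multiplier_high,
              format(x$multiplier_low * x$gdp_per_capita, big.mark = ","),
              format(x$multiplier_high * x$gdp_per_capita, big.mark = ",")))
  invisible(x)
}
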