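#' Deterministic 64-eye fixture cohort matching the published tallies
#'
#' A synthetic, deterministically constructed cohort whose marginal counts
#' equal the published per-eye tallies of the modelled study: 20
#' preservative-free eyes (14 monotherapy, 6 combination) vs 44
#' preservative-containing (20/24); monotherapy classes 25 PG + 9 BB;
#' combination compositions 6:8:5:2:9; good control in 15 (ST), 23 (TMS)
#' and 2 (NIBUT) of 64 eyes; sex 25:39, age bands 10:28:21:5, side 30:34,
#' duration 27:27:10. Joint cross-tabulations (e.g. which eyes are good on
#' which test, or the arm-by-composition split) are **not** published, so
#' the row-wise assignment here is an arbitrary deterministic fill; only
#' the marginals are data.
#'
#' Measurement values are fixed representatives strictly on the assigned
#' side of each default threshold (ST 15/5 mm, TMS 1/5, NIBUT 18/8 s).
#' Therapy lines reference [example_price_list()].
#'
#' @return A validated cohort tibble of 64 eyes.
#' @examples
#' summarize_cohort(reference_cohort()) |>
#'   dplyr::filter(indicator == "therapy_type_free")
#' @export
reference_cohort <- function() {
  n <- 64
  free <- rep(c(TRUE, FALSE), c(20, 44))
  mono <- rep(c(TRUE, FALSE, TRUE, FALSE), c(14, 6, 20, 24))
  mono_class <- rep(NA_character_, n)
  mono_class[free & mono] <- rep(c("PG", "BB"), c(10, 4))
  mono_class[!free & mono] <- rep(c("PG", "BB"), c(15, 5))
  combos <- rep(c("PG+BB", "BB+CAI", "PG+CAI", "CAI+A2A", "PG+BB+CAI"),
                c(6, 8, 5, 2, 9))
  combo_type <- rep(NA_character_, n)
  combo_type[!mono] <- combos

  st_good <- seq_len(n) <= 15
  tms_good <- seq_len(n) <= 23
  nibut_good <- seq_len(n) <= 2

  product_for <- function(cl, pf) {
    base <- c(PG = "lat", BB = "tim", CAI = "dorz", A2A = "brim")[[cl]]
    if (pf) paste0(base, "_pf") else base
  }
  therapies <- vapply(seq_len(n), function(i) {
    classes <- if (mono[i]) mono_class[i] else strsplit(combo_type[i], "+", fixed = TRUE)[[1]]
    lines <- vapply(classes, function(cl) {
      sprintf("%s:%s:%g:%s", cl, class_inn[[cl]], class_doses[[cl]],
              product_for(cl, free[i]))
    }, character(1))
    paste(c(lines, "AT:hypromellose:4:tears"), collapse = ";")
  }, character(1))

  eye_record(
    eye_id = sprintf("ref%03d", seq_len(n)),
    patient_id = sprintf("refpat%03d", seq_len(n)),
    side = rep(c("left", "right"), c(30, 34)),
    sex = rep(c("male", "female"), c(25, 39)),
    age_years = rep(c(55L, 65L, 75L, 82L), c(10, 28, 21, 5)),
    duration_band = rep(c("lt1y", "1to5y", "5to10y"), c(27, 27, 10)),
    st_mm = ifelse(st_good, 15, 5),
    tms_score = ifelse(tms_good, 1L, 5L),
    nibut_s = ifelse(nibut_good, 18, 8),
    preservative_free = free,
    therapies = therapies
  )
}

#' Example drug price list
#'
#' A small illustrative price list resolving every product referenced by
#' [reference_cohort()]. The two latanoprost pack prices are the published
#' Bulgarian register values (23.5 BGN preservative-containing, 50.4 BGN
#' preservative-free); every other price and all pack sizes (doses per
#' pack) are plausible fixtures invented for examples and tests, not
#' published facts.
#'
#' @return A price-list tibble.
#' @examples
#' example_price_list()
#' @export
example_price_list <- function() {
  dplyr::bind_rows(
    drug_product("lat", "latanoprost", "PG", FALSE, 23.5, 80),
    drug_product("lat_pf", "latanoprost", "PG", TRUE, 50.4, 80),
    drug_product("tim", "timolol", "BB", FALSE, 8.0, 80),
    drug_product("tim_pf", "timolol", "BB", TRUE, 15.0, 80),
    drug_product("dorz", "dorzolamide", "CAI", FALSE, 18.0, 80),
    drug_product("dorz_pf", "dorzolamide", "CAI", TRUE, 30.0, 80),
    drug_product("brim", "brimonidine", "A2A", FALSE, 16.0, 80),
    drug_product("brim_pf", "brimonidine", "A2A", TRUE, 28.0, 80),
    drug_product("tears", "hypromellose", "AT", TRUE, 12.0, 100)
  )
}

#' Example decision tree built from the fixture cohort
#'
#' Convenience wrapper: [build_tree_from_cohort()] applied to
#' [reference_cohort()] with [example_price_list()], TMS as the effect
#' measure.
#'
#' @param effect_measure `"TMS"`, `"NIBUT"` or `"ST"`.
#' @return A `ce_tree`.
#' @examples
#' rollback(reference_tree())
#' @export
reference_tree <- function(effect_measure = "TMS") {
  build_tree_from_cohort(reference_cohort(), example_price_list(),
                         effect_measure = effect_measure)
}
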