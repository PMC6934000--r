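#' Build a per-eye cohort tibble
#'
#' The unit of analysis is the affected **eye**, not the patient: one row per
#' eye, with `patient_id` retained only for provenance. Therapy is stored in
#' a compact one-column syntax so a cohort round-trips through a single CSV:
#' lines separated by `";"`, each line `class:inn:doses_per_day:product_id`
#' with `class` one of `PG` (prostaglandin analogue), `BB` (beta-blocker),
#' `CAI` (carbonic anhydrase inhibitor), `A2A` (alpha-2 adrenergic agonist)
#' or `AT` (artificial tears, supplemental dry-eye therapy). `product_id`
#' keys into a price list (see [read_price_list()]) and may be empty when no
#' costing is needed.
#'
#' @param eye_id,patient_id Opaque identifiers (character).
#' @param side `"left"` or `"right"`.
#' @param sex `"male"` or `"female"`.
#' @param age_years Integer age in years.
#' @param duration_band Disease duration band: `"lt1y"`, `"1to5y"` or
#'   `"5to10y"`.
#' @param st_mm Schirmer test, mm (non-negative).
#' @param tms_score Total meiboscore, integer 0--6.
#' @param nibut_s Non-invasive tear break-up time, seconds (non-negative).
#' @param preservative_free Logical: `TRUE` iff **all** glaucoma lines are
#'   preservative-free formulations.
#' @param therapies Compact therapy string (see Details); at least one
#'   glaucoma line is required.
#' @return A tibble with one row per eye.
#' @examples
#' eye_record("e1", "p1", "left", "female", 67, "1to5y",
#'            st_mm = 8, tms_score = 4, nibut_s = 9,
#'            preservative_free = TRUE,
#'            therapies = "PG:latanoprost:1:lat_pf;AT:hypromellose:4:tears")
#' @export
eye_record <- function(eye_id, patient_id, side, sex, age_years,
                       duration_band, st_mm, tms_score, nibut_s,
                       preservative_free, therapies) {
  tibble::tibble(
    eye_id = as.character(eye_id), patient_id = as.character(patient_id),
    side = side, sex = sex, age_years = as.integer(age_years),
    duration_band = duration_band, st_mm = as.numeric(st_mm),
    tms_score = as.integer(tms_score), nibut_s = as.numeric(nibut_s),
    preservative_free = preservative_free, therapies = therapies
  )
}

cohort_columns <- function() {
  c("eye_id", "patient_id", "side", "sex", "age_years", "duration_band",
    "st_mm", "tms_score", "nibut_s", "preservative_free", "therapies")
}

#' Expand the compact therapy column into one row per therapy line
#'
#' @param cohort A cohort tibble (see [eye_record()]).
#' @return A tibble with columns `eye_id`, `drug_class`, `inn`,
#'   `doses_per_day`, `product_id` and `is_glaucoma` (FALSE for artificial
#'   tears).
#' @examples
#' therapy_lines(reference_cohort())
#' @export
therapy_lines <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) {
    return(tibble::tibble(eye_id = character(), drug_class = character(),
                          inn = character(), doses_per_day = double(),
                          product_id = character(), is_glaucoma = logical()))
  }
  per_eye <- strsplit(cohort$therapies, ";", fixed = TRUE)
  nl <- lengths(per_eye)
  flat <- unlist(per_eye, use.names = FALSE)
  keep <- flat != ""
  fields <- stringr::str_split_fixed(flat[keep], ":", 4)
  product <- fields[, 4]
  tibble::tibble(
    eye_id = rep(cohort$eye_id, nl)[keep],
    drug_class = fields[, 1],
    inn = fields[, 2],
    doses_per_day = suppressWarnings(as.numeric(fields[, 3])),
    product_id = dplyr::if_else(product == "", NA_character_, product),
    is_glaucoma = fields[, 1] %in% GLAUCOMA_CLASSES
  )
}

# number of glaucoma therapy lines per eye, in cohort row order; pass
# precomputed `lines` to avoid re-parsing large cohorts
n_glaucoma_lines <- function(cohort, lines = NULL) {
  lines <- lines %||% therapy_lines(cohort)
  sum_by_eye(as.numeric(lines$is_glaucoma), lines$eye_id, cohort$eye_id)
}

# fast grouped sum aligned to `all_ids` (0 for ids with no rows)
sum_by_eye <- function(x, ids, all_ids) {
  s <- rowsum(x, ids)
  out <- s[match(all_ids, rownames(s)), 1]
  out[is.na(out)] <- 0
  unname(out)
}

#' Validate a cohort of per-eye records
#'
#' Checks column presence, enum levels, the 0--6 meiboscore range,
#' non-negative measurements, the presence of at least one glaucoma therapy
#' line per eye and positive dosing. In `"study"` mode (the default) ages
#' must also fall in the 30--85 inclusion window of the observational design;
#' `"lenient"` mode drops that restriction.
#'
#' @param cohort A cohort tibble.
#' @param mode `"study"` or `"lenient"`.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   first offending row and field.
#' @examples
#' validate_cohort(reference_cohort())
#' @export
validate_cohort <- function(cohort, mode = c("study", "lenient")) {
  mode <- match.arg(mode)
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame")
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  fail <- function(row, field, why) {
    abort(sprintf("invalid cohort row %d: field `%s` %s", row, field, why))
  }
  check_enum <- function(field, levels) {
    bad <- which(!(cohort[[field]] %in% levels))
    if (length(bad) > 0) {
      fail(bad[1], field, paste0("must be one of ",
                                 paste(levels, collapse = ", ")))
    }
  }
  check_num <- function(field, lo, hi = Inf, integer = FALSE) {
    v <- cohort[[field]]
    bad <- which(!is.finite(v) | v < lo | v > hi |
                   (integer & is.finite(v) & v != round(v)))
    if (length(bad) > 0) {
      fail(bad[1], field,
           sprintf("must be %san in-range value [%g, %g]; got %s",
                   if (integer) "an integer and " else "", lo, hi,
                   format(v[bad[1]])))
    }
  }
  na_id <- which(is.na(cohort$eye_id) | cohort$eye_id == "")
  if (length(na_id) > 0) fail(na_id[1], "eye_id", "must be non-empty")
  if (anyDuplicated(cohort$eye_id)) {
    fail(anyDuplicated(cohort$eye_id), "eye_id", "must be unique")
  }
  check_enum("side", c("left", "right"))
  check_enum("sex", c("male", "female"))
  check_enum("duration_band", c("lt1y", "1to5y", "5to10y"))
  if (mode == "study") check_num("age_years", 30, 85, integer = TRUE)
  else check_num("age_years", 0, 150, integer = TRUE)
  check_num("st_mm", 0)
  check_num("tms_score", 0, 6, integer = TRUE)
  check_num("nibut_s", 0)
  bad_pf <- which(is.na(cohort$preservative_free) |
                    !is.logical(cohort$preservative_free))
  if (length(bad_pf) > 0) fail(bad_pf[1], "preservative_free", "must be TRUE/FALSE")

  lines <- therapy_lines(cohort)
  bad_class <- which(!(lines$drug_class %in% ALL_CLASSES))
  if (length(bad_class) > 0) {
    row <- match(lines$eye_id[bad_class[1]], cohort$eye_id)
    fail(row, "therapies",
         sprintf("has unknown drug class `%s`", lines$drug_class[bad_class[1]]))
  }
  bad_dose <- which(!is.finite(lines$doses_per_day) | lines$doses_per_day <= 0)
  if (length(bad_dose) > 0) {
    row <- match(lines$eye_id[bad_dose[1]], cohort$eye_id)
    fail(row, "therapies", "has a non-positive or missing doses_per_day")
  }
  ngl <- n_glaucoma_lines(cohort, lines)
  if (any(ngl == 0)) {
    fail(which(ngl == 0)[1], "therapies",
         "must contain at least one glaucoma line (PG/BB/CAI/A2A)")
  }
  invisible(cohort)
}

#' Classify per-eye disease control against the three tear-film tests
#'
#' Appends logical columns `st_good`, `tms_good`, `nibut_good` and
#' `overall_good` (the conjunction: effective therapy means good control in
#' all three indicators). Good control is ST above its threshold, TMS
#' *below* its threshold, NIBUT above its threshold; boundary values follow
#' the thresholds object's `boundary` convention (poor by default).
#'
#' @param cohort A cohort tibble with `st_mm`, `tms_score`, `nibut_s`.
#' @param thresholds A [control_thresholds()] object.
#' @return The cohort with four logical columns appended.
#' @examples
#' classify_control(reference_cohort()) |> dplyr::count(overall_good)
#' @export
classify_control <- function(cohort, thresholds = control_thresholds()) {
  stopifnot(inherits(thresholds, "control_thresholds"), is.data.frame(cohort))
  for (field in c("st_mm", "tms_score", "nibut_s")) {
    if (!field %in% names(cohort)) {
      abort(sprintf("missing measurement column `%s`", field))
    }
    if (anyNA(cohort[[field]])) {
      abort(sprintf("invalid cohort row %d: field `%s` is missing",
                    which(is.na(cohort[[field]]))[1], field))
    }
  }
  gt <- function(x, thr) if (thresholds$boundary == "good") x >= thr else x > thr
  lt <- function(x, thr) if (thresholds$boundary == "good") x <= thr else x < thr
  cohort |>
    dplyr::mutate(
      st_good = gt(.data$st_mm, thresholds$st_threshold_mm),
      tms_good = lt(.data$tms_score, thresholds$tms_threshold),
      nibut_good = gt(.data$nibut_s, thresholds$nibut_threshold_s),
      overall_good = .data$st_good & .data$tms_good & .data$nibut_good
    )
}

#' Summarise a cohort: demographics, control rates and prescribing strata
#'
#' One tidy row per (indicator, level): exact counts, the denominator the
#' share is taken over, the raw fraction and the percentage rounded to one
#' decimal. Demographic indicators and per-test control rates use the whole
#' cohort as denominator; the therapy-mix rows within each preservative arm
#' use the arm size; monotherapy class shares use the number of monotherapy
#' eyes and combination composition shares the number of combination eyes.
#' Mono vs combination therapy is derived from the count of glaucoma lines
#' (1 vs 2 or more); fixed-dose combinations are entered as multiple lines.
#'
#' @param cohort A non-empty, valid cohort tibble.
#' @param thresholds A [control_thresholds()] object.
#' @return A tibble with columns `indicator`, `level`, `n`, `denom`, `frac`,
#'   `pct`, carrying the cohort size in attribute `n_eyes`.
#' @examples
#' summarize_cohort(reference_cohort()) |>
#'   dplyr::filter(indicator == "mono_class")
#' @export
summarize_cohort <- function(cohort, thresholds = control_thresholds()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) abort("empty cohort")
  validate_cohort(cohort, mode = "lenient")
  n <- nrow(cohort)
  cls <- classify_control(cohort, thresholds)
  cls$age_band <- cut(cls$age_years, breaks = c(-Inf, 49, 60, 70, 80, Inf),
                      labels = c("below50", "50to60", "61to70", "71to80",
                                 "above80"))
  cls$therapy_type <- ifelse(n_glaucoma_lines(cohort) >= 2,
                             "combination", "monotherapy")
  cls$arm <- ifelse(cls$preservative_free, "free", "non_free")

  tally <- function(values, indicator, levels, denom) {
    counts <- table(factor(values, levels = levels))
    tibble::tibble(indicator = indicator, level = levels,
                   n = as.integer(counts), denom = denom)
  }
  good_poor <- function(flag) ifelse(flag, "good", "poor")

  rows <- list(
    tally(cls$sex, "sex", c("male", "female"), n),
    tally(as.character(cls$age_band), "age_band",
          c("below50", "50to60", "61to70", "71to80", "above80"), n),
    tally(cls$side, "side", c("left", "right"), n),
    tally(cls$duration_band, "duration",
          c("lt1y", "1to5y", "5to10y"), n),
    tally(good_poor(cls$st_good), "control_st", c("good", "poor"), n),
    tally(good_poor(cls$tms_good), "control_tms", c("good", "poor"), n),
    tally(good_poor(cls$nibut_good), "control_nibut", c("good", "poor"), n),
    tally(good_poor(cls$overall_good), "control_overall", c("good", "poor"), n),
    tally(cls$arm, "preservative", c("free", "non_free"), n),
    tally(cls$therapy_type, "therapy_type", c("monotherapy", "combination"), n)
  )

  # therapy mix within each preservative arm (Table-2-style row percentages)
  for (a in c("free", "non_free")) {
    sub <- cls[cls$arm == a, ]
    if (nrow(sub) > 0) {
      rows <- c(rows, list(
        tally(sub$therapy_type, paste0("therapy_type_", a),
              c("monotherapy", "combination"), nrow(sub))
      ))
    }
  }

  mono_ids <- cohort$eye_id[cls$therapy_type == "monotherapy"]
  combo_ids <- cohort$eye_id[cls$therapy_type == "combination"]
  lines <- therapy_lines(cohort) |> dplyr::filter(.data$is_glaucoma)
  if (length(mono_ids) > 0) {
    mono_cls <- lines$drug_class[match(mono_ids, lines$eye_id)]
    rows <- c(rows, list(
      tally(mono_cls, "mono_class", GLAUCOMA_CLASSES, length(mono_ids))
    ))
  }
  if (length(combo_ids) > 0) {
    combos <- lines |>
      dplyr::filter(.data$eye_id %in% combo_ids) |>
      dplyr::group_by(.data$eye_id) |>
      dplyr::summarise(combo = combo_label(.data$drug_class), .groups = "drop")
    rows <- c(rows, list(
      tally(combos$combo, "combo_type", sort(unique(combos$combo)),
            length(combo_ids))
    ))
  }

  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(frac = .data$n / .data$denom,
                  pct = round(100 * .data$n / .data$denom, 1))
  attr(out, "n_eyes") <- n
  out
}

# canonical combination label: classes sorted in PG < BB < CAI < A2A order
combo_label <- function(classes) {
  paste(GLAUCOMA_CLASSES[sort(match(unique(classes), GLAUCOMA_CLASSES))],
        collapse = "+")
}

#' Read / write a cohort CSV
#'
#' The file format is UTF-8 CSV with a `"."` decimal separator and the
#' column schema of [eye_record()]. Reading validates every row (lenient
#' age mode so historical files load; pass the result through
#' [validate_cohort()] with `mode = "study"` to enforce the 30--85 inclusion
#' window). Writing then reading gives back identical records.
#'
#' @param path File path.
#' @param delim Field delimiter (default `","`).
#' @param mode Validation mode passed to [validate_cohort()].
#' @return `read_cohort()`: a validated cohort tibble (zero rows for a
#'   header-only file). `write_cohort()`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(reference_cohort(), f)
#' nrow(read_cohort(f))
#' @export
read_cohort <- function(path, delim = ",", mode = "lenient") {
  # parse problems become errors below, so readr's own warning is redundant
  cohort <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      eye_id = readr::col_character(), patient_id = readr::col_character(),
      side = readr::col_character(), sex = readr::col_character(),
      age_years = readr::col_integer(), duration_band = readr::col_character(),
      st_mm = readr::col_double(), tms_score = readr::col_integer(),
      nibut_s = readr::col_double(),
      preservative_free = readr::col_logical(),
      therapies = readr::col_character()
    )
  ))
  prob <- readr::problems(cohort)
  if (nrow(prob) > 0) {
    # readr reports file rows; subtract the header to name the record
    abort(sprintf("malformed cohort file row %d: column `%s` (expected %s, got %s)",
                  prob$row[1] - 1L, names(cohort)[prob$col[1]] %||% prob$col[1],
                  prob$expected[1], prob$actual[1]))
  }
  if (nrow(cohort) > 0) validate_cohort(cohort, mode = mode)
  cohort
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, mode = "lenient")
  readr::write_csv(cohort[, cohort_columns()], path, progress = FALSE)
  invisible(path)
}
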