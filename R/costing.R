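#' Build or read a drug-product price list
#'
#' Prices are per pack in BGN; `doses_per_pack` is the number of single-eye
#' doses (drops) one pack yields. Pack sizes are not part of published price
#' registers, so the schema requires them explicitly.
#'
#' @param product_id,inn Identifiers (character).
#' @param drug_class One of `PG`, `BB`, `CAI`, `A2A`, `AT`.
#' @param preservative_free Logical.
#' @param pack_price_bgn Pack price in BGN, non-negative.
#' @param doses_per_pack Positive integer doses per pack.
#' @return A price-list tibble.
#' @examples
#' drug_product("lat_pf", "latanoprost", "PG", TRUE, 50.4, 80)
#' @export
drug_product <- function(product_id, inn, drug_class, preservative_free,
                         pack_price_bgn, doses_per_pack) {
  tibble::tibble(product_id = as.character(product_id), inn = as.character(inn),
                 drug_class = drug_class,
                 preservative_free = preservative_free,
                 pack_price_bgn = as.numeric(pack_price_bgn),
                 doses_per_pack = as.integer(doses_per_pack))
}

validate_prices <- function(prices) {
  need <- c("product_id", "inn", "drug_class", "preservative_free",
            "pack_price_bgn", "doses_per_pack")
  missing_cols <- setdiff(need, names(prices))
  if (length(missing_cols) > 0) {
    abort(paste0("price list is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(prices$pack_price_bgn) | prices$pack_price_bgn < 0)) {
    abort("price list: `pack_price_bgn` must be non-negative")
  }
  if (any(!is.finite(prices$doses_per_pack) | prices$doses_per_pack < 1)) {
    abort("price list: `doses_per_pack` must be >= 1")
  }
  if (anyDuplicated(prices$product_id)) {
    abort(sprintf("price list: duplicated product_id `%s`",
                  prices$product_id[anyDuplicated(prices$product_id)]))
  }
  invisible(prices)
}

#' @rdname drug_product
#' @param path CSV path with the schema above.
#' @export
read_price_list <- function(path) {
  prices <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              product_id = readr::col_character(),
                              inn = readr::col_character(),
                              drug_class = readr::col_character(),
                              preservative_free = readr::col_logical(),
                              pack_price_bgn = readr::col_double(),
                              doses_per_pack = readr::col_integer()
                            ))
  validate_prices(prices)
  prices
}

#' @rdname drug_product
#' @param prices A price-list tibble.
#' @export
write_price_list <- function(prices, path) {
  validate_prices(prices)
  readr::write_csv(prices, path, progress = FALSE)
  invisible(path)
}

round_bgn <- function(x) round(x + 1e-9 * sign(x), 2)

#' Yearly cost of one therapy line
#'
#' The yearly cost multiplies the prescribed dosing regimen by the unit
#' price: `doses_per_day * year_days / doses_per_pack * pack_price`,
#' rounded to 0.01 BGN. `dispensing = "prorated"` (the default) prices
#' partial packs continuously; `"whole_packs"` charges every started pack,
#' reflecting real dispensing.
#'
#' @param doses_per_day Prescribed doses per day (positive).
#' @param pack_price_bgn Pack price, BGN.
#' @param doses_per_pack Doses per pack.
#' @param year_days Days per year (default 365, no leap handling).
#' @param dispensing `"prorated"` or `"whole_packs"`.
#' @return Yearly cost in BGN, rounded to 0.01.
#' @examples
#' yearly_line_cost(2, 10, 100)        # 73.00
#' yearly_line_cost(1, 50.40, 365)     # 50.40
#' @export
yearly_line_cost <- function(doses_per_day, pack_price_bgn, doses_per_pack,
                             year_days = 365,
                             dispensing = c("prorated", "whole_packs")) {
  dispensing <- match.arg(dispensing)
  if (any(doses_per_day <= 0)) abort("`doses_per_day` must be positive")
  if (any(pack_price_bgn < 0)) abort("`pack_price_bgn` must be non-negative")
  if (any(doses_per_pack < 1)) abort("`doses_per_pack` must be >= 1")
  packs <- doses_per_day * year_days / doses_per_pack
  if (dispensing == "whole_packs") packs <- ceiling(packs - 1e-9)
  round_bgn(packs * pack_price_bgn)
}

#' Yearly glaucoma and dry-eye cost per eye
#'
#' Sums [yearly_line_cost()] over each eye's glaucoma lines; the dry-eye
#' cost is the artificial-tears line cost (0 when no tears are prescribed).
#'
#' @param cohort A cohort tibble whose therapy lines carry resolvable
#'   `product_id`s.
#' @param prices A price-list tibble.
#' @inheritParams yearly_line_cost
#' @return The cohort's `eye_id` and `preservative_free` columns with
#'   `glaucoma_cost` and `dry_eye_cost` (BGN/year) appended.
#' @examples
#' study <- generate_cohort(default_config())
#' eye_yearly_cost(study$cohort, study$prices)
#' @export
eye_yearly_cost <- function(cohort, prices, year_days = 365,
                            dispensing = c("prorated", "whole_packs")) {
  dispensing <- match.arg(dispensing)
  validate_prices(prices)
  lines <- therapy_lines(cohort)
  unresolved <- lines$product_id[is.na(lines$product_id) |
                                   !(lines$product_id %in% prices$product_id)]
  if (length(unresolved) > 0) {
    bad <- lines[is.na(lines$product_id) |
                   !(lines$product_id %in% prices$product_id), ][1, ]
    abort(sprintf("unknown product_ref `%s` on therapy line `%s:%s` of eye %s",
                  bad$product_id %||% "<missing>", bad$drug_class, bad$inn,
                  bad$eye_id))
  }
  idx <- match(lines$product_id, prices$product_id)
  lines$cost <- yearly_line_cost(lines$doses_per_day,
                                 prices$pack_price_bgn[idx],
                                 prices$doses_per_pack[idx],
                                 year_days = year_days, dispensing = dispensing)
  tibble::tibble(
    eye_id = cohort$eye_id,
    preservative_free = cohort$preservative_free,
    glaucoma_cost = round_bgn(sum_by_eye(lines$cost * lines$is_glaucoma,
                                         lines$eye_id, cohort$eye_id)),
    dry_eye_cost = round_bgn(sum_by_eye(lines$cost * !lines$is_glaucoma,
                                        lines$eye_id, cohort$eye_id))
  )
}

#' Split a yearly cost into payer reimbursement and patient co-payment
#'
#' Glaucoma therapy is reimbursed at `reimbursement_rate` (50% for the
#' Bulgarian NHIF); dry-eye therapy (artificial tears) is not reimbursed at
#' all, so it falls entirely on the co-payment. Shares are rounded to 0.01
#' BGN with largest-remainder reconciliation so `reimbursed + copay` equals
#' the rounded total exactly; a half-cent tie goes to the reimbursed share.
#'
#' @param glaucoma_cost,dry_eye_cost Yearly costs in BGN (non-negative,
#'   vectorised).
#' @param reimbursement_rate Payer share of glaucoma cost in `[0, 1]`.
#' @return A tibble with `total`, `reimbursed`, `copay` (BGN/year).
#' @examples
#' split_payment(321.77, 0)        # 160.89 / 160.88
#' split_payment(321.77, 179.93)   # copay 340.81
#' @export
split_payment <- function(glaucoma_cost, dry_eye_cost = 0,
                          reimbursement_rate = 0.5) {
  if (any(glaucoma_cost < 0) || any(dry_eye_cost < 0)) {
    abort("costs must be non-negative")
  }
  if (reimbursement_rate < 0 || reimbursement_rate > 1) {
    abort("`reimbursement_rate` must be in [0, 1]")
  }
  n <- max(length(glaucoma_cost), length(dry_eye_cost))
  g <- rep_len(glaucoma_cost, n); d <- rep_len(dry_eye_cost, n)
  total_cents <- round(100 * g) + round(100 * d)
  reimb_exact <- reimbursement_rate * round(100 * g)
  reimb_cents <- floor(reimb_exact + 1e-9)
  # largest-remainder: the leftover cent (if any) goes to the share with the
  # larger fractional remainder; ties favour the reimbursed share
  copay_exact <- total_cents - reimb_exact
  copay_cents <- floor(copay_exact + 1e-9)
  short <- total_cents - reimb_cents - copay_cents
  rem_reimb <- reimb_exact - reimb_cents
  rem_copay <- copay_exact - copay_cents
  give_reimb <- short > 0 & rem_reimb >= rem_copay - 1e-9
  reimb_cents <- reimb_cents + ifelse(give_reimb, short, 0)
  copay_cents <- copay_cents + ifelse(short > 0 & !give_reimb, short, 0)
  tibble::tibble(total = total_cents / 100, reimbursed = reimb_cents / 100,
                 copay = copay_cents / 100)
}

#' Median/SD cost summary by preservative arm
#'
#' Reports the median and standard deviation (n-1 denominator) of yearly
#' glaucoma cost overall and within the preservative-free and
#' preservative-containing arms, plus the dry-eye (artificial tears) cost.
#' Medians of even-length samples are midpoint means. An empty arm is
#' reported with `n = 0` and missing statistics, never as zero cost; a
#' single-eye arm has a median but no SD.
#'
#' @inheritParams eye_yearly_cost
#' @return A tibble with `component`, `n`, `median`, `sd` (BGN/year).
#' @examples
#' study <- generate_cohort(default_config())
#' summarize_costs(study$cohort, study$prices)
#' @export
summarize_costs <- function(cohort, prices, year_days = 365,
                            dispensing = c("prorated", "whole_packs")) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) abort("empty cohort")
  costs <- eye_yearly_cost(cohort, prices, year_days = year_days,
                           dispensing = dispensing)
  one <- function(component, x) {
    tibble::tibble(component = component, n = length(x),
                   median = if (length(x) > 0) median(x) else NA_real_,
                   sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  dplyr::bind_rows(
    one("dry_eye", costs$dry_eye_cost[costs$dry_eye_cost > 0]),
    one("glaucoma_total", costs$glaucoma_cost),
    one("glaucoma_free", costs$glaucoma_cost[costs$preservative_free]),
    one("glaucoma_non_free", costs$glaucoma_cost[!costs$preservative_free])
  )
}
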