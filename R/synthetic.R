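#' Configuration for the synthetic POAG+DE cohort generator
#'
#' Defaults reproduce the categorical structure and cost scale of the
#' observed 64-eye Bulgarian cohort the package models: 20/64 eyes on
#' preservative-free therapy, 14/20 of those on monotherapy (20/44 in the
#' preservative-containing arm), monotherapy class mix 25:9:0:0
#' (PG:BB:CAI:A2A), the five observed combination compositions in ratio
#' 6:8:5:2:9, marginal good-control probabilities 15/64 (ST), 23/64 (TMS),
#' 2/64 (NIBUT), and yearly costs drawn from log-normals parameterised to
#' the reported medians/SDs (glaucoma: 320.97/133.18 BGN free arm,
#' 322.14/203.76 non-free; artificial tears: 179.93/9.36). Demographics
#' (sex 25:39, age bands 10:28:21:5, side 30:34, duration 27:27:10) follow
#' the reported per-eye tallies; eyes are sampled independently, so
#' within-patient eye pairing is not reproduced.
#'
#' @param n_eyes Cohort size (default 64).
#' @param p_preservative_free P(preservative-free strategy).
#' @param p_mono_given_free,p_mono_given_nonfree P(monotherapy | arm).
#' @param mono_class_weights Named weights over `PG`, `BB`, `CAI`, `A2A`.
#' @param combo_weights Named weights over combination compositions
#'   (canonical `+`-joined class labels in PG, BB, CAI, A2A order).
#' @param control_probs Named good-control probabilities for `ST`, `TMS`,
#'   `NIBUT`; either one marginal vector or a list with elements `free` and
#'   `non_free` for arm-specific probabilities.
#' @param cost_params List of `free`, `non_free`, `dry_eye`, each
#'   `list(median =, sd =)` in BGN/year.
#' @param sex_weights,age_band_weights,side_weights,duration_weights Named
#'   demographic weights.
#' @param measurement_ranges Intervals the measurements are drawn from,
#'   uniformly, strictly on the sampled side of each threshold:
#'   `st_good`, `st_poor`, `nibut_good`, `nibut_poor` (length-2 numeric),
#'   `tms_good`, `tms_poor` (integer candidate sets).
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return A validated list of class `cohort_config`.
#' @examples
#' default_config()
#' cohort_config(n_eyes = 200, seed = 42)
#' @export
cohort_config <- function(n_eyes = 64,
                          p_preservative_free = 20 / 64,
                          p_mono_given_free = 14 / 20,
                          p_mono_given_nonfree = 20 / 44,
                          mono_class_weights = c(PG = 25, BB = 9, CAI = 0, A2A = 0),
                          combo_weights = c("PG+BB" = 6, "BB+CAI" = 8,
                                            "PG+CAI" = 5, "CAI+A2A" = 2,
                                            "PG+BB+CAI" = 9),
                          control_probs = c(ST = 15 / 64, TMS = 23 / 64,
                                            NIBUT = 2 / 64),
                          cost_params = list(
                            free = list(median = 320.97, sd = 133.18),
                            non_free = list(median = 322.14, sd = 203.76),
                            dry_eye = list(median = 179.93, sd = 9.36)
                          ),
                          sex_weights = c(male = 25, female = 39),
                          age_band_weights = c("50to60" = 10, "61to70" = 28,
                                               "71to80" = 21, "above80" = 5),
                          side_weights = c(left = 30, right = 34),
                          duration_weights = c(lt1y = 27, "1to5y" = 27,
                                               "5to10y" = 10),
                          measurement_ranges = list(
                            st_good = c(10.5, 20), st_poor = c(0, 9.5),
                            nibut_good = c(14.5, 25), nibut_poor = c(1, 13.5),
                            tms_good = 0:2, tms_poor = 3:6
                          ),
                          seed = 2019L) {
  cfg <- structure(
    list(n_eyes = as.integer(n_eyes),
         p_preservative_free = p_preservative_free,
         p_mono_given_free = p_mono_given_free,
         p_mono_given_nonfree = p_mono_given_nonfree,
         mono_class_weights = mono_class_weights,
         combo_weights = combo_weights,
         control_probs = control_probs,
         cost_params = cost_params,
         sex_weights = sex_weights,
         age_band_weights = age_band_weights,
         side_weights = side_weights,
         duration_weights = duration_weights,
         measurement_ranges = measurement_ranges,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_config <- function() cohort_config()

validate_config <- function(cfg) {
  chk_prob <- function(field, p) {
    if (any(!is.finite(p) | p < 0 | p > 1)) {
      abort(sprintf("invalid config field `%s`: probabilities must be in [0, 1]", field))
    }
  }
  chk_weights <- function(field, w) {
    if (any(!is.finite(w) | w < 0) || sum(w) == 0) {
      abort(sprintf("invalid config field `%s`: weights must be non-negative and not all zero", field))
    }
  }
  if (!is.finite(cfg$n_eyes) || cfg$n_eyes < 1) {
    abort("invalid config field `n_eyes`: must be >= 1")
  }
  chk_prob("p_preservative_free", cfg$p_preservative_free)
  chk_prob("p_mono_given_free", cfg$p_mono_given_free)
  chk_prob("p_mono_given_nonfree", cfg$p_mono_given_nonfree)
  if (!setequal(names(cfg$mono_class_weights), GLAUCOMA_CLASSES)) {
    abort("invalid config field `mono_class_weights`: must name PG, BB, CAI, A2A")
  }
  chk_weights("mono_class_weights", cfg$mono_class_weights)
  chk_weights("combo_weights", cfg$combo_weights)
  cp <- cfg$control_probs
  if (is.list(cp)) {
    if (!all(c("free", "non_free") %in% names(cp))) {
      abort("invalid config field `control_probs`: list form needs `free` and `non_free`")
    }
    for (arm in c("free", "non_free")) {
      if (!setequal(names(cp[[arm]]), EFFECT_MEASURES)) {
        abort("invalid config field `control_probs`: must name ST, TMS, NIBUT")
      }
      chk_prob("control_probs", cp[[arm]])
    }
  } else {
    if (!setequal(names(cp), EFFECT_MEASURES)) {
      abort("invalid config field `control_probs`: must name ST, TMS, NIBUT")
    }
    chk_prob("control_probs", cp)
  }
  for (arm in c("free", "non_free", "dry_eye")) {
    p <- cfg$cost_params[[arm]]
    if (is.null(p$median) || p$median <= 0 || is.null(p$sd) || p$sd < 0) {
      abort(sprintf("invalid config field `cost_params$%s`: need median > 0 and sd >= 0", arm))
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n_eyes = %d, seed = %d\n", x$n_eyes, x$seed))
  cat(sprintf("  P(free) = %.4f; P(mono | free) = %.3f; P(mono | non-free) = %.3f\n",
              x$p_preservative_free, x$p_mono_given_free, x$p_mono_given_nonfree))
  cat(sprintf("  good-control P: %s\n",
              paste(names(unlist(x$control_probs)),
                    round(unlist(x$control_probs), 3),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Log-normal parameters from a target median and SD
#'
#' Yearly therapy costs are positive and right-skewed (the combination-
#' therapy tail), so the generator draws them from a log-normal. Given a
#' target median m and standard deviation s, `mu = log(m)` and
#' `sigma^2 = log(x)` where `x = (1 + sqrt(1 + 4 s^2 / m^2)) / 2` solves
#' the quadratic `(x - 1) x m^2 = s^2` implied by the log-normal variance
#' formula; the solution is exact.
#'
#' @param median Target median (> 0).
#' @param sd Target standard deviation (>= 0).
#' @return A list with `meanlog` and `sdlog` for [stats::rlnorm()].
#' @examples
#' p <- lognormal_from_median_sd(321.77, 181)
#' exp(p$meanlog)  # the median
#' @export
lognormal_from_median_sd <- function(median, sd) {
  stopifnot(median > 0, sd >= 0)
  x <- (1 + sqrt(1 + 4 * sd^2 / median^2)) / 2
  list(meanlog = log(median), sdlog = sqrt(log(x)))
}

class_inn <- c(PG = "latanoprost", BB = "timolol", CAI = "dorzolamide",
               A2A = "brimonidine", AT = "hypromellose")
class_doses <- c(PG = 1, BB = 2, CAI = 2, A2A = 2, AT = 4)

#' Generate a synthetic patient-eye cohort with its price list
#'
#' Each eye is drawn hierarchically: strategy arm, mono vs combination,
#' therapeutic class or combination composition, per-test control status,
#' then measurements consistent with the sampled control flags (uniform on
#' the configured interval strictly on the sampled side of each threshold)
#' and yearly costs from the configured log-normals. Because drawn costs
#' determine the synthetic pack prices, the generator also emits the price
#' list that reproduces each eye's drawn cost through [eye_yearly_cost()]
#' (one synthetic product per therapy line, equal cost split across an
#' eye's glaucoma lines, 100-dose packs). All eyes receive artificial
#' tears, as observed.
#'
#' Generation is deterministic given `config$seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ce_study` with elements `cohort` (validated
#'   cohort tibble), `prices` (price-list tibble) and `config`.
#' @examples
#' study <- generate_cohort(default_config())
#' nrow(study$cohort)
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_eyes
  sample_w <- function(n, w) {
    sample(names(w), n, replace = TRUE, prob = w / sum(w))
  }
  free <- runif(n) < cfg$p_preservative_free
  mono <- runif(n) < ifelse(free, cfg$p_mono_given_free, cfg$p_mono_given_nonfree)
  mono_class <- rep(NA_character_, n)
  combo_type <- rep(NA_character_, n)
  if (any(mono)) mono_class[mono] <- sample_w(sum(mono), cfg$mono_class_weights)
  if (any(!mono)) combo_type[!mono] <- sample_w(sum(!mono), cfg$combo_weights)

  ctrl_p <- function(test) {
    if (is.list(cfg$control_probs)) {
      ifelse(free, cfg$control_probs$free[[test]],
             cfg$control_probs$non_free[[test]])
    } else rep(cfg$control_probs[[test]], n)
  }
  st_good <- runif(n) < ctrl_p("ST")
  tms_good <- runif(n) < ctrl_p("TMS")
  nibut_good <- runif(n) < ctrl_p("NIBUT")
  mr <- cfg$measurement_ranges
  draw_unif <- function(flag, good, poor) {
    ifelse(flag, runif(n, good[1], good[2]), runif(n, poor[1], poor[2]))
  }
  st_mm <- round(draw_unif(st_good, mr$st_good, mr$st_poor), 1)
  nibut_s <- round(draw_unif(nibut_good, mr$nibut_good, mr$nibut_poor), 1)
  tms_score <- ifelse(tms_good,
                      sample(mr$tms_good, n, replace = TRUE),
                      sample(mr$tms_poor, n, replace = TRUE))

  ln <- function(p) lognormal_from_median_sd(p$median, p$sd)
  lf <- ln(cfg$cost_params$free); lnf <- ln(cfg$cost_params$non_free)
  lde <- ln(cfg$cost_params$dry_eye)
  g_cost <- ifelse(free,
                   stats::rlnorm(n, lf$meanlog, lf$sdlog),
                   stats::rlnorm(n, lnf$meanlog, lnf$sdlog))
  de_cost <- stats::rlnorm(n, lde$meanlog, lde$sdlog)

  sex <- sample_w(n, cfg$sex_weights)
  band <- sample_w(n, cfg$age_band_weights)
  band_lo <- c("50to60" = 50, "61to70" = 61, "71to80" = 71, "above80" = 81)
  band_hi <- c("50to60" = 60, "61to70" = 70, "71to80" = 80, "above80" = 85)
  age <- band_lo[band] + floor(runif(n) * (band_hi[band] - band_lo[band] + 1))
  side <- sample_w(n, cfg$side_weights)
  duration <- sample_w(n, cfg$duration_weights)

  eye_id <- sprintf("eye%06d", seq_len(n))
  # long format: one row per glaucoma therapy line, vectorised
  composition <- ifelse(mono, mono_class, combo_type)
  classes_list <- strsplit(composition, "+", fixed = TRUE)
  n_lines <- lengths(classes_list)
  eye_idx <- rep(seq_len(n), n_lines)
  cl <- unlist(classes_list, use.names = FALSE)
  line_k <- sequence(n_lines)
  # equal cost split across an eye's glaucoma lines; pack price chosen so the
  # prorated yearly line cost reproduces the drawn share (100-dose packs)
  share <- g_cost[eye_idx] / n_lines[eye_idx]
  pid <- sprintf("%s_g%d", eye_id[eye_idx], line_k)
  line_str <- sprintf("%s:%s:%g:%s", cl, class_inn[cl], class_doses[cl], pid)
  pid_at <- sprintf("%s_at", eye_id)
  # lines of one eye are contiguous in line_str; join them without split()
  starts <- cumsum(c(1L, n_lines[-n]))
  glaucoma_part <- line_str[starts]
  for (k in seq_len(max(n_lines))[-1]) {
    more <- n_lines >= k
    if (any(more)) {
      glaucoma_part[more] <- paste(glaucoma_part[more],
                                   line_str[starts[more] + k - 1L], sep = ";")
    }
  }
  therapies <- sprintf("%s;AT:%s:%g:%s", glaucoma_part, class_inn[["AT"]],
                       class_doses[["AT"]], pid_at)

  prices <- dplyr::bind_rows(
    tibble::tibble(product_id = pid, inn = unname(class_inn[cl]),
                   drug_class = cl, preservative_free = free[eye_idx],
                   pack_price_bgn = unname(share * 100 / (class_doses[cl] * 365)),
                   doses_per_pack = 100L),
    tibble::tibble(product_id = pid_at, inn = class_inn[["AT"]],
                   drug_class = "AT", preservative_free = TRUE,
                   pack_price_bgn = de_cost * 100 / (class_doses[["AT"]] * 365),
                   doses_per_pack = 100L)
  )
  cohort <- tibble::tibble(
    eye_id = eye_id, patient_id = sprintf("pat%06d", seq_len(n)),
    side = side, sex = sex, age_years = as.integer(age),
    duration_band = duration, st_mm = st_mm,
    tms_score = as.integer(tms_score), nibut_s = nibut_s,
    preservative_free = free, therapies = therapies
  )
  validate_cohort(cohort, mode = "study")
  structure(list(cohort = cohort, prices = prices, config = cfg),
            class = "ce_study")
}

#' @export
print.ce_study <- function(x, ...) {
  cat(sprintf("<ce_study> %d eyes (%d preservative-free), %d priced products\n",
              nrow(x$cohort), sum(x$cohort$preservative_free), nrow(x$prices)))
  invisible(x)
}

#' Read / write a cohort-generator config as YAML
#'
#' Round-trips: serialise, parse, serialise is byte-identical.
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_cohort_config()`: `path` invisibly;
#'   `read_cohort_config()`: a validated `cohort_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_cohort_config(default_config(), f)
#' read_cohort_config(f)$n_eyes
#' @export
write_cohort_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$mono_class_weights <- as.list(x$mono_class_weights)
  x$combo_weights <- as.list(x$combo_weights)
  x$control_probs <- if (is.list(x$control_probs)) {
    lapply(x$control_probs, as.list)
  } else as.list(x$control_probs)
  x$sex_weights <- as.list(x$sex_weights)
  x$age_band_weights <- as.list(x$age_band_weights)
  x$side_weights <- as.list(x$side_weights)
  x$duration_weights <- as.list(x$duration_weights)
  # 17 significant digits: doubles survive the YAML round-trip exactly
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  unl <- function(v) unlist(v)
  cp <- x$control_probs
  cp <- if (all(c("free", "non_free") %in% names(cp))) lapply(cp, unl) else unl(cp)
  cohort_config(
    n_eyes = x$n_eyes, p_preservative_free = x$p_preservative_free,
    p_mono_given_free = x$p_mono_given_free,
    p_mono_given_nonfree = x$p_mono_given_nonfree,
    mono_class_weights = unl(x$mono_class_weights),
    combo_weights = unl(x$combo_weights),
    control_probs = cp,
    cost_params = x$cost_params,
    sex_weights = unl(x$sex_weights),
    age_band_weights = unl(x$age_band_weights),
    side_weights = unl(x$side_weights),
    duration_weights = unl(x$duration_weights),
    measurement_ranges = lapply(x$measurement_ranges, unl),
    seed = x$seed
  )
}
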