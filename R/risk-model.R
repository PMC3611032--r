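#' Construct a risk factor
#'
#' Risk factors are either elementary — lab analytes whose values come from a
#' panel — or secondary: demographic attributes (age) or clinical
#' observations (symptoms) inferred by a doctor.
#'
#' @param id Identifier; for elementary factors, must match the panel's
#'   analyte name.
#' @param name Human-readable name; defaults to `id`.
#' @param category `"elementary"` or `"secondary"`.
#' @param source `"lab_analyte"` (elementary only), `"demographic"` or
#'   `"clinical_observation"` (secondary only).
#' @param units Measurement units, e.g. `"mg/dL"`; empty for unitless factors.
#' @return A `risk_factor`.
#' @export
risk_factor <- function(id, name = id, category = c("elementary", "secondary"),
                        source = c("lab_analyte", "demographic", "clinical_observation"),
                        units = "") {
  category <- match.arg(category)
  source <- match.arg(source)
  if (category == "elementary" && source != "lab_analyte") {
    stop_ahpdx("invalid_profile", "elementary factor ", id, " must have source lab_analyte")
  }
  if (category == "secondary" && source == "lab_analyte") {
    stop_ahpdx("invalid_profile", "secondary factor ", id,
               " must have source demographic or clinical_observation")
  }
  structure(list(id = as.character(id), name = as.character(name),
                 category = category, source = source,
                 units = as.character(units)),
            class = "risk_factor")
}

#' Construct a reference range
#'
#' A (possibly sex- and age-stratified) low/high interval for a factor. A
#' value strictly beyond either bound activates the factor.
#'
#' @param factor_id Factor this range applies to.
#' @param sex `"male"`, `"female"` or `"any"`.
#' @param age_min,age_max Optional age bounds in years (inclusive).
#' @param low,high Optional bounds; at least one must be given, and
#'   `low < high` when both are.
#' @return A `reference_range`.
#' @export
reference_range <- function(factor_id, sex = "any", age_min = NULL,
                            age_max = NULL, low = NULL, high = NULL) {
  sex <- match.arg(sex, c("male", "female", "any"))
  if (is.null(low) && is.null(high)) {
    stop_ahpdx("invalid_profile", "range for ", factor_id, " needs low and/or high")
  }
  if (!is.null(low) && !is.null(high) && low >= high) {
    stop_ahpdx("invalid_profile", "range for ", factor_id, ": low must be < high")
  }
  if (!is.null(age_min) && !is.null(age_max) && age_min > age_max) {
    stop_ahpdx("invalid_profile", "range for ", factor_id, ": age_min > age_max")
  }
  structure(list(factor_id = as.character(factor_id), sex = sex,
                 age_min = age_min, age_max = age_max,
                 low = low, high = high),
            class = "reference_range")
}

#' Construct a condition profile
#'
#' Bundles everything the engine needs to score one illness: the risk
#' factors, the physician's pairwise judgments (or precomputed weights), the
#' reference ranges, and the positivity/critical thresholds.
#'
#' @param condition Condition name.
#' @param factors List of `risk_factor` objects (order fixes weight order).
#' @param judgments Pairwise judgments as accepted by [build_matrix()];
#'   may be `NULL` if `weights` is given.
#' @param weights Optional precomputed numeric weights (summing to 1, in
#'   factor order), bypassing the AHP derivation.
#' @param ranges List of `reference_range` objects. Every lab/demographic
#'   factor needs at least one; clinical-observation factors activate from
#'   the panel's observations block instead.
#' @param diagnosis_threshold Score percentage at or above which the
#'   classification is positive; system default 80, physician-configurable.
#' @param critical_threshold Score percentage at or above which the case is
#'   flagged critical; default 95; must be `>= diagnosis_threshold`.
#' @return A `condition_profile`.
#' @export
condition_profile <- function(condition, factors, judgments = NULL,
                              weights = NULL, ranges = list(),
                              diagnosis_threshold = 80,
                              critical_threshold = 95) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  ids <- vapply(factors, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop_ahpdx("invalid_profile", "duplicate factor ids")
  if (is.null(judgments) && is.null(weights)) {
    stop_ahpdx("invalid_profile", "profile needs judgments or precomputed weights")
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(ids) || abs(sum(weights) - 1) > 1e-9 ||
        any(weights < 0)) {
      stop_ahpdx("invalid_profile",
                 "weights must be non-negative, one per factor, summing to 1")
    }
  }
  if (!(diagnosis_threshold > 0 && diagnosis_threshold <= critical_threshold &&
        critical_threshold <= 100)) {
    stop_ahpdx("invalid_profile",
               "need 0 < diagnosis_threshold <= critical_threshold <= 100")
  }
  range_ids <- vapply(ranges, function(r) r$factor_id, character(1))
  for (f in factors) {
    if (f$source != "clinical_observation" && !(f$id %in% range_ids)) {
      stop_ahpdx("invalid_profile", "factor ", f$id, " has no reference range")
    }
  }
  if (!all(range_ids %in% ids)) {
    stop_ahpdx("invalid_profile", "range for unknown factor: ",
               paste(setdiff(range_ids, ids), collapse = ", "))
  }
  structure(
    list(condition = as.character(condition), factors = factors,
         judgments = judgments, weights = weights, ranges = ranges,
         diagnosis_threshold = diagnosis_threshold,
         critical_threshold = critical_threshold),
    class = "condition_profile"
  )
}

profile_factor_ids <- function(profile) {
  vapply(profile$factors, function(f) f$id, character(1))
}

#' Derive (or retrieve) a profile's weight vector
#'
#' Runs [principal_weights()] on the profile's judgments, or wraps its
#' precomputed weights.
#'
#' @param profile A `condition_profile`.
#' @param tol,max_iter Passed to [principal_weights()].
#' @return A `weight_vector`.
#' @export
profile_weights <- function(profile, tol = 1e-6, max_iter = 20L) {
  ids <- profile_factor_ids(profile)
  if (!is.null(profile$weights)) {
    return(structure(list(factors = ids, weights = profile$weights,
                          iterations_used = 0L, converged = TRUE),
                     class = "weight_vector"))
  }
  m <- build_matrix(ids, profile$judgments)
  principal_weights(m, tol = tol, max_iter = max_iter)
}

#' Read a condition profile from a YAML/JSON config file
#'
#' Expected keys: `condition`; `factors` (list of `id`, optional `name`,
#' `category`, `source`, `units`); `judgments` (list of `[i, j, ratio]`
#' triples, ratios as numbers or `"p/q"` strings) or `weights`; `ranges`
#' (list of `factor_id`, optional `sex`, `age_min`, `age_max`, `low`,
#' `high`); `diagnosis_threshold`; `critical_threshold`.
#'
#' @param path Config file path.
#' @return A `condition_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_ahpdx("not_found", "profile file not found: ", path)
  cfg <- yaml::read_yaml(path)
  factors <- lapply(cfg$factors, function(f) {
    risk_factor(id = f$id, name = f$name %||% f$id,
                category = f$category %||% "elementary",
                source = f$source %||% "lab_analyte",
                units = f$units %||% "")
  })
  ranges <- lapply(cfg$ranges, function(r) {
    reference_range(factor_id = r$factor_id, sex = r$sex %||% "any",
                    age_min = r$age_min, age_max = r$age_max,
                    low = r$low, high = r$high)
  })
  condition_profile(
    condition = cfg$condition %||% "unnamed",
    factors = factors, judgments = cfg$judgments, weights = cfg$weights,
    ranges = ranges,
    diagnosis_threshold = cfg$diagnosis_threshold %||% 80,
    critical_threshold = cfg$critical_threshold %||% 95
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the applicable reference range for a patient
#'
#' Picks the most specific range matching the patient's sex and age: a range
#' with the exact sex beats `sex = "any"`, and among equally sex-specific
#' candidates a narrower age span beats a wider one (missing age bounds count
#' as unbounded). Deterministic: remaining ties go to the earlier range.
#'
#' @param factor_id Factor to look up.
#' @param sex Patient sex, `"male"` or `"female"`.
#' @param age Patient age in years (may be `NULL` if no range is
#'   age-stratified).
#' @param ranges List of `reference_range` objects.
#' @return The selected `reference_range`.
#' @export
resolve_range <- function(factor_id, sex, age, ranges) {
  cand <- Filter(function(r) r$factor_id == factor_id, ranges)
  matches <- Filter(function(r) {
    if (!(r$sex == "any" || r$sex == sex)) return(FALSE)
    if (!is.null(r$age_min) && (is.null(age) || age < r$age_min)) return(FALSE)
    if (!is.null(r$age_max) && (is.null(age) || age > r$age_max)) return(FALSE)
    TRUE
  }, cand)
  if (length(matches) == 0L) {
    stop_ahpdx("missing_range", "no reference range for factor ", factor_id,
               " matching sex=", sex, ", age=",
               if (is.null(age)) "NA" else format(age))
  }
  sex_exact <- vapply(matches, function(r) r$sex != "any", logical(1))
  span <- vapply(matches, function(r) {
    (r$age_max %||% Inf) - (r$age_min %||% -Inf)
  }, numeric(1))
  matches[[order(!sex_exact, span)[1]]]
}

#' Is a value beyond its reference range?
#'
#' Activation is strict: a value activates only when strictly below `low` or
#' strictly above `high`; a value exactly on a bound is in range.
#'
#' @param value Finite numeric measurement.
#' @param range A `reference_range`.
#' @return Logical flag.
#' @export
evaluate_activation <- function(value, range) {
  stopifnot(is.finite(value))
  (!is.null(range$low) && value < range$low) ||
    (!is.null(range$high) && value > range$high)
}

#' Age in whole years at a reference date
#'
#' @param birth_date,at Dates.
#' @return Integer age (completed years).
#' @export
age_at <- function(birth_date, at) {
  birth_date <- as.Date(birth_date); at <- as.Date(at)
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(at)
  age <- a$year - b$year
  if (a$mon < b$mon || (a$mon == b$mon && a$mday < b$mday)) age <- age - 1L
  as.integer(age)
}

#' Evaluate factor activation for one patient and panel
#'
#' For each elementary factor, looks up the analyte in the panel, resolves
#' the applicable reference range and tests activation. Demographic factors
#' (id `"Age"`, case-insensitive, or any `source = "demographic"` factor
#' named `Age`) are evaluated from the patient's age at the panel's
#' collection date. Clinical-observation factors activate from the panel's
#' observations block. Factors absent from the panel are inactive and flagged
#' unobserved, so incomplete panels are explicit rather than silently
#' optimistic.
#'
#' @param profile A `condition_profile`.
#' @param panel A `lab_panel` belonging to the patient.
#' @param patient A `patient`.
#' @return An `activation_map`: data frame with one row per profile factor
#'   and columns `factor_id`, `active`, `observed`, `value`.
#' @export
activation_map <- function(profile, panel, patient) {
  stopifnot(inherits(profile, "condition_profile"),
            inherits(panel, "lab_panel"), inherits(patient, "patient"))
  if (!identical(panel$patient_id, patient$patient_id)) {
    stop_ahpdx("invalid_profile", "panel ", panel$panel_id,
               " does not belong to patient ", patient$patient_id)
  }
  age <- age_at(patient$birth_date, panel$collected)
  rows <- lapply(profile$factors, function(f) {
    active <- FALSE; observed <- FALSE; value <- NA_real_
    if (f$source == "lab_analyte") {
      hit <- match(f$id, panel$analytes$name)
      if (!is.na(hit)) {
        observed <- TRUE
        value <- panel$analytes$value[hit]
        punits <- panel$analytes$units[hit]
        if (nzchar(f$units) && nzchar(punits) &&
            tolower(f$units) != tolower(punits)) {
          stop_ahpdx("unit_mismatch", "factor ", f$id, ": profile units '",
                     f$units, "' vs panel units '", punits, "'")
        }
        rng <- resolve_range(f$id, patient$sex, age, profile$ranges)
        active <- evaluate_activation(value, rng)
      }
    } else if (f$source == "demographic") {
      observed <- TRUE
      value <- as.numeric(age)
      rng <- resolve_range(f$id, patient$sex, age, profile$ranges)
      active <- evaluate_activation(value, rng)
    } else { # clinical_observation
      hit <- match(f$id, panel$observations$name)
      if (!is.na(hit)) {
        observed <- TRUE
        active <- isTRUE(panel$observations$present[hit])
        value <- as.numeric(active)
      }
    }
    data.frame(factor_id = f$id, active = active, observed = observed,
               value = value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activation_map", class(out))
  out
}
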