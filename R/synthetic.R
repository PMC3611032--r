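# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic cohort
#'
#' Describes a cohort with controlled ground truth: a fixed fraction of
#' patients (applied as an exact count, not coin flips) receive the
#' positive-case recipe — a set of factors forced strictly out of range —
#' while the rest sample strictly inside all applicable ranges.
#'
#' @param n_patients Cohort size.
#' @param prevalence Fraction in `[0, 1]` of truth-positive patients;
#'   `round(n_patients * prevalence)` patients get the recipe.
#' @param recipe Character vector of factor ids forced out of range in
#'   positive cases. For the cohort's positives to be detectable, the
#'   recipe's combined weight must reach the profile's diagnosis threshold.
#' @param seed Integer seed; cohorts are deterministic given the seed.
#' @param margin Out-of-range forcing margin as a fraction of the bound's
#'   magnitude (default 0.10): forced values sit at `bound * (1 +/- margin)`,
#'   well clear of the strict-activation boundary.
#' @param age_range Two integers; patient ages are sampled uniformly in this
#'   interval (default 25-45 years).
#' @param intervals Optional named list `factor_id -> c(lo, hi)` overriding
#'   the in-range sampling interval derived from each factor's resolved
#'   reference range.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prevalence, recipe, seed,
                        margin = 0.10, age_range = c(25L, 45L),
                        intervals = NULL) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1,
            margin > 0, length(age_range) == 2L)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, recipe = as.character(recipe),
                 seed = as.integer(seed), margin = margin,
                 age_range = as.integer(age_range), intervals = intervals),
            class = "cohort_spec")
}

# Strictly-in-range sampling interval for a resolved range; one-sided ranges
# get a finite companion bound at half/1.5x the stated bound.
inrange_interval <- function(rng) {
  lo <- rng$low %||% (rng$high * 0.5)
  hi <- rng$high %||% (rng$low * 1.5)
  c(lo, hi)
}

forced_value <- function(rng, margin) {
  if (!is.null(rng$high)) rng$high + margin * max(abs(rng$high), 1)
  else rng$low - margin * max(abs(rng$low), 1)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given the spec's seed. Demographics (sex, age) are sampled
#' uniformly; each elementary factor's value is sampled strictly inside the
#' range that applies to the generated patient, except recipe factors of
#' truth-positive patients, which are forced strictly beyond a bound by the
#' spec's margin. A recipe naming a demographic factor forces the patient's
#' age beyond that factor's range instead.
#'
#' @param profile A `condition_profile`.
#' @param spec A `cohort_spec`.
#' @param enforce_detectable If `TRUE` (default), error when the recipe's
#'   combined weight is below the diagnosis threshold, since such positives
#'   could never be detected. Relax only to study that regime deliberately.
#' @return List of `list(patient, panel, truth)` records; `truth` is logical.
#' @export
generate_cohort <- function(profile, spec, enforce_detectable = TRUE) {
  stopifnot(inherits(profile, "condition_profile"), inherits(spec, "cohort_spec"))
  ids <- profile_factor_ids(profile)
  unknown <- setdiff(spec$recipe, ids)
  if (length(unknown) > 0L) {
    stop_ahpdx("config", "recipe references unknown factor: ",
               paste(unknown, collapse = ", "))
  }
  w <- profile_weights(profile)
  recipe_weight <- sum(w$weights[w$factors %in% spec$recipe])
  if (enforce_detectable && recipe_weight < profile$diagnosis_threshold / 100) {
    stop_ahpdx("config", "recipe weight ", format(recipe_weight),
               " is below diagnosis threshold ",
               profile$diagnosis_threshold, "% - positives would be undetectable")
  }

  n <- spec$n_patients
  n_pos <- as.integer(round(n * spec$prevalence))
  collected <- as.Date("2013-03-01")

  with_local_seed(spec$seed, {
    pos_idx <- if (n_pos > 0L) sample.int(n, n_pos) else integer()
    lapply(seq_len(n), function(i) {
      truth <- i %in% pos_idx
      sex <- sample(c("male", "female"), 1L)
      age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1L)
      demo_recipe <- Filter(function(f) f$source == "demographic" &&
                              f$id %in% spec$recipe, profile$factors)
      if (truth && length(demo_recipe) > 0L) {
        rng <- resolve_range(demo_recipe[[1]]$id, sex, NULL, profile$ranges)
        age <- as.integer(ceiling(forced_value(rng, spec$margin)))
      }
      pat <- patient(sprintf("SYN%04d", i), sex,
                     birth_date = collected - round(age * 365.25) - 10,
                     registered = collected - 30)
      an <- do.call(rbind, lapply(profile$factors, function(f) {
        if (f$source != "lab_analyte") return(NULL)
        rng <- resolve_range(f$id, sex, age, profile$ranges)
        value <- if (truth && f$id %in% spec$recipe) {
          forced_value(rng, spec$margin)
        } else {
          iv <- spec$intervals[[f$id]] %||% inrange_interval(rng)
          eps <- 0.01 * (iv[2] - iv[1])
          stats::runif(1, iv[1] + eps, iv[2] - eps)
        }
        data.frame(name = f$id, value = value, units = f$units,
                   stringsAsFactors = FALSE)
      }))
      obs <- do.call(rbind, lapply(profile$factors, function(f) {
        if (f$source != "clinical_observation") return(NULL)
        data.frame(name = f$id, present = truth && f$id %in% spec$recipe,
                   stringsAsFactors = FALSE)
      }))
      pan <- lab_panel(pat$patient_id, collected, analytes = an,
                       observations = obs)
      list(patient = pat, panel = pan, truth = truth)
    })
  })
}

#' Evaluate the diagnosis engine on a labelled cohort
#'
#' Runs [batch_diagnose()] over the cohort and tallies the classifications
#' against the generator's truth labels.
#'
#' @param profile A `condition_profile`.
#' @param cohort Output of [generate_cohort()].
#' @return A `confusion_summary`: TP/FP/TN/FN counts plus `sensitivity`
#'   (`NA` when there are no truth positives) and `specificity` (`NA` when
#'   there are no truth negatives).
#' @export
evaluate_cohort <- function(profile, cohort) {
  records <- lapply(cohort, function(r) list(patient = r$patient, panel = r$panel))
  out <- batch_diagnose(profile, records)
  if (length(out$errors) > 0L) {
    stop_ahpdx("config", "cohort evaluation failed on ",
               length(out$errors), " record(s): ", out$errors[[1]]$message)
  }
  truth <- vapply(cohort, function(r) r$truth, logical(1))
  pred <- vapply(out$results, function(r) r$classification == "positive", logical(1))
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
  structure(
    list(true_positive = tp, false_positive = fp,
         true_negative = tn, false_negative = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Confusion summary: TP", x$true_positive, "FP", x$false_positive,
      "TN", x$true_negative, "FN", x$false_negative, "\n")
  cat(sprintf("  sensitivity %s  specificity %s\n",
              format(x$sensitivity), format(x$specificity)))
  invisible(x)
}
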