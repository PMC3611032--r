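#' Diagnosis score from weights and activation
#'
#' The score is 100 times the sum of the priority weights of the activated
#' factors: each out-of-range factor contributes its full weight. Computed
#' from unrounded weights; the integer-percentage view is presentation only.
#'
#' @param weights A `weight_vector`.
#' @param activation An `activation_map` over the same factor ids.
#' @return Score in `[0, 100]` (unrounded).
#' @export
dx_score <- function(weights, activation) {
  if (!setequal(weights$factors, activation$factor_id) ||
      length(weights$factors) != nrow(activation)) {
    stop_ahpdx("profile_inconsistency",
               "weights and activation cover different factor sets")
  }
  act <- activation$active[match(weights$factors, activation$factor_id)]
  100 * sum(weights$weights[act])
}

#' Classify a score against a positivity threshold
#'
#' @param score Score percentage in `[0, 100]`.
#' @param threshold Positivity threshold in `(0, 100]`. Inclusive: a score
#'   exactly at the threshold is positive.
#' @return `"positive"` or `"negative"`.
#' @export
classify <- function(score, threshold) {
  stopifnot(score >= 0, score <= 100, threshold > 0, threshold <= 100)
  if (score >= threshold) "positive" else "negative"
}

#' Create a notification event
#'
#' @param kind `"new_result"`, `"diagnosis"` or `"critical"`.
#' @param patient_id Patient identifier.
#' @param ref Condition name or panel reference the event is about.
#' @param timestamp POSIXct timestamp (UTC); defaults to the current time.
#' @param summary Brief human-readable description.
#' @return A `notification_event`.
#' @export
notification_event <- function(kind = c("new_result", "diagnosis", "critical"),
                               patient_id, ref, timestamp = Sys.time(),
                               summary = "") {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, patient_id = as.character(patient_id),
         ref = as.character(ref),
         timestamp = as.POSIXct(timestamp, tz = "UTC"),
         summary = as.character(summary)),
    class = "notification_event"
  )
}

#' Diagnose one patient from one lab panel
#'
#' Composes the full pipeline: derive the profile's AHP weights, build the
#' activation map, sum activated weights into a score, classify against the
#' diagnosis threshold, and flag critical cases at the critical threshold.
#' Critical cases carry a `"critical"` notification event so the doctor can
#' be alerted immediately.
#'
#' @param profile A `condition_profile`.
#' @param patient A `patient`.
#' @param panel A `lab_panel` belonging to the patient.
#' @param threshold Optional override of the profile's diagnosis threshold.
#' @param weights Optional precomputed `weight_vector` (used by
#'   [batch_diagnose()] to derive weights once per profile).
#' @return A `diagnosis_result`: `patient_id`, `condition`, `panel_date`,
#'   `per_factor` (data frame with `factor_id`, `weight_percent`, `active`,
#'   `observed`), `score` (2-decimal), `classification`, `critical`, and
#'   `events` (list of `notification_event`, non-empty only when critical).
#' @export
diagnose <- function(profile, patient, panel, threshold = NULL, weights = NULL) {
  if (is.null(weights)) weights <- profile_weights(profile)
  threshold <- threshold %||% profile$diagnosis_threshold
  act <- activation_map(profile, panel, patient)
  raw <- dx_score(weights, act)
  cls <- classify(raw, threshold)
  critical <- raw >= profile$critical_threshold
  pct <- to_percentages(weights)
  per_factor <- data.frame(
    factor_id = weights$factors,
    weight_percent = as.integer(pct[weights$factors]),
    active = act$active[match(weights$factors, act$factor_id)],
    observed = act$observed[match(weights$factors, act$factor_id)],
    stringsAsFactors = FALSE
  )
  events <- list()
  if (critical) {
    events <- list(notification_event(
      "critical", patient$patient_id, profile$condition,
      timestamp = as.POSIXct(paste(format(panel$collected), "00:00:00"), tz = "UTC"),
      summary = paste0("Critical diagnosis for ", profile$condition,
                       "; please contact your doctor.")
    ))
  }
  structure(
    list(patient_id = patient$patient_id, condition = profile$condition,
         panel_date = panel$collected, per_factor = per_factor,
         score = round(raw, 2), score_raw = raw,
         classification = cls, critical = critical, events = events),
    class = "diagnosis_result"
  )
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat("Diagnosis:", x$condition, "| patient", x$patient_id,
      "| panel", format(x$panel_date), "\n")
  for (i in seq_len(nrow(x$per_factor))) {
    r <- x$per_factor[i, ]
    cat(sprintf("  %-16s %3d%%  %s\n", r$factor_id, r$weight_percent,
                if (!r$observed) "unobserved"
                else if (r$active) "ACTIVE" else "in range"))
  }
  cat(sprintf("  score %.2f%% -> %s%s\n", x$score, x$classification,
              if (x$critical) " (CRITICAL)" else ""))
  invisible(x)
}

#' Diagnose a batch of patient/panel records
#'
#' Weights are derived once per profile. Per-record failures (for example a
#' unit mismatch) are collected and reported without aborting the batch.
#'
#' @param profile A `condition_profile`.
#' @param records List of `list(patient = , panel = )` pairs.
#' @return List with `results` (diagnosis results in input order; failed
#'   records are omitted), `events` (critical notification events) and
#'   `errors` (list of `list(index, message)` for failed records).
#' @export
batch_diagnose <- function(profile, records) {
  weights <- profile_weights(profile)
  results <- list(); events <- list(); errors <- list()
  for (k in seq_along(records)) {
    rec <- records[[k]]
    res <- tryCatch(
      diagnose(profile, rec$patient, rec$panel, weights = weights),
      ahpdx_error = function(e) e
    )
    if (inherits(res, "ahpdx_error")) {
      errors[[length(errors) + 1L]] <- list(index = k, message = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
      events <- c(events, res$events)
    }
  }
  list(results = results, events = events, errors = errors)
}
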