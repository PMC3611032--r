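# Shared fixtures: the four-factor hyperglycemia example and random-case
# generators used by the property tests.

table1_factors <- c("HDL", "LDL", "Triglyceridea", "Age")

table1_judgments <- list(
  list("HDL", "LDL", 3), list("HDL", "Triglyceridea", 7), list("HDL", "Age", 7),
  list("LDL", "Triglyceridea", 5), list("LDL", "Age", 5),
  list("Triglyceridea", "Age", 1)
)

table1_matrix <- function() build_matrix(table1_factors, table1_judgments)

# Converged priority weights of the four-factor matrix (verified against a
# generic dominant-eigenvector computation in test-ahp-core.R).
table2_weights <- c(0.582726, 0.282482, 0.067396, 0.067396)

hyperglycemia_profile <- function(diagnosis_threshold = 80,
                                  critical_threshold = 95) {
  condition_profile(
    condition = "hyperglycemia",
    factors = list(
      risk_factor("HDL", "HDL cholesterol", "elementary", "lab_analyte", "mg/dL"),
      risk_factor("LDL", "LDL cholesterol", "elementary", "lab_analyte", "mg/dL"),
      risk_factor("Triglyceridea", "Triglycerides", "elementary", "lab_analyte", "mg/dL"),
      risk_factor("Age", "Age", "secondary", "demographic", "years")
    ),
    judgments = table1_judgments,
    ranges = list(
      reference_range("HDL", sex = "male", high = 40),
      reference_range("HDL", sex = "female", high = 50),
      reference_range("LDL", low = 80),
      reference_range("Triglyceridea", low = 40, high = 150),
      reference_range("Age", high = 60)
    ),
    diagnosis_threshold = diagnosis_threshold,
    critical_threshold = critical_threshold
  )
}

# Male patient, age 35 at the worked-example panel date.
example_patient <- function() patient("P001", "male", "1977-06-02", "2012-11-01")

# HDL over 40 and LDL under 80 (both out of range for a male); the other two
# factors in range.
example_panel <- function(hdl = 45, ldl = 70, tri = 120) {
  lab_panel("P001", "2013-02-15",
            analytes = data.frame(
              name = c("HDL", "LDL", "Triglyceridea"),
              value = c(hdl, ldl, tri),
              units = c("mg/dL", "mg/dL", "mg/dL")))
}

# Random full judgment set over n factors, ratios drawn from the Saaty
# levels and their reciprocals.
random_judgments <- function(factors) {
  n <- length(factors)
  levels <- c(1, 3, 5, 7, 9)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- sample(levels, 1)
      if (runif(1) < 0.5) r <- 1 / r
      out[[length(out) + 1L]] <- list(factors[i], factors[j], r)
    }
  }
  out
}

# Perfectly consistent comparison matrix from a known positive weight vector.
consistent_matrix <- function(w, factors = paste0("f", seq_along(w))) {
  m <- outer(w, w, "/")
  dimnames(m) <- list(factors, factors)
  structure(m, class = c("pairwise_matrix", "matrix", "array"))
}

# Independent oracle: dominant eigenvector via the generic eigendecomposition.
dominant_eigvec <- function(m) {
  e <- eigen(unclass(m))
  i <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

random_panel <- function(patient_id = "RND", n_analytes = 3) {
  nm <- sort(sample(paste0("A", 1:20), n_analytes))
  lab_panel(
    patient_id, as.Date("2013-01-01") + sample(0:365, 1),
    analytes = data.frame(name = nm,
                          value = round(runif(n_analytes, 1, 500), 3),
                          units = sample(c("mg/dL", "mmol/L", ""), n_analytes,
                                         replace = TRUE)),
    observations = data.frame(name = c("fatigue", "thirst"),
                              present = runif(2) < 0.5),
    notes = sample(c("", "notes with <angle> & ampersand", "ok"), 1)
  )
}
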