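test_that("resolve_range prefers the exact-sex range over sex=any", {
  ranges <- list(reference_range("HDL", sex = "male", high = 40),
                 reference_range("HDL", sex = "female", high = 50))
  r <- resolve_range("HDL", "male", 35, ranges)
  expect_equal(r$sex, "male")
  expect_equal(r$high, 40)
  one <- list(reference_range("X", sex = "any", low = 1, high = 2))
  expect_identical(resolve_range("X", "female", 20, one), one[[1]])
  expect_error(resolve_range("HDL", "female",
                             35, list(reference_range("HDL", sex = "male", high = 40))),
               class = "ahpdx_missing_range")
})

test_that("resolve_range prefers narrower age spans and is deterministic", {
  ranges <- list(reference_range("X", age_min = 0, age_max = 120, high = 10),
                 reference_range("X", age_min = 30, age_max = 40, high = 5))
  expect_equal(resolve_range("X", "male", 35, ranges)$high, 5)
  expect_equal(resolve_range("X", "male", 50, ranges)$high, 10)
  set.seed(5)
  for (rep in 1:25) {
    rs <- list(reference_range("X", sex = "any", high = 1),
               reference_range("X", sex = sample(c("male", "female"), 1), high = 2))
    ord <- sample(2)
    pick <- resolve_range("X", rs[[2]]$sex, 40, rs[ord])
    expect_equal(pick$high, 2) # sex-exact always beats any
  }
})

test_that("activation is strict at the bounds and monotone in the value", {
  high40 <- reference_range("HDL", high = 40)
  low80 <- reference_range("LDL", low = 80)
  expect_true(evaluate_activation(45, high40))
  expect_true(evaluate_activation(70, low80))
  expect_false(evaluate_activation(40, high40))
  expect_false(evaluate_activation(80, low80))
  set.seed(13)
  for (rep in 1:30) {
    v <- runif(1, 0, 100)
    if (evaluate_activation(v, high40)) {
      expect_true(evaluate_activation(v + runif(1, 0, 50), high40))
    }
    if (evaluate_activation(v, low80)) {
      expect_true(evaluate_activation(v - runif(1, 0, 50), low80))
    }
  }
})

test_that("the worked-example panel activates exactly HDL and LDL", {
  act <- activation_map(hyperglycemia_profile(), example_panel(), example_patient())
  expect_setequal(act$factor_id, table1_factors)
  expect_setequal(act$factor_id[act$active], c("HDL", "LDL"))
  expect_true(all(act$observed))
})

test_that("a fully in-range panel activates nothing", {
  act <- activation_map(hyperglycemia_profile(),
                        example_panel(hdl = 35, ldl = 90, tri = 120),
                        example_patient())
  expect_false(any(act$active))
})

test_that("factors missing from the panel are inactive and flagged unobserved", {
  pan <- lab_panel("P001", "2013-02-15",
                   analytes = data.frame(name = c("HDL", "LDL"),
                                         value = c(45, 70),
                                         units = c("mg/dL", "mg/dL")))
  act <- activation_map(hyperglycemia_profile(), pan, example_patient())
  tri <- act[act$factor_id == "Triglyceridea", ]
  expect_false(tri$active)
  expect_false(tri$observed)
  expect_setequal(act$factor_id[act$active], c("HDL", "LDL"))
})

test_that("unit mismatches between profile and panel are rejected", {
  pan <- example_panel()
  pan$analytes$units[pan$analytes$name == "HDL"] <- "mmol/L"
  expect_error(activation_map(hyperglycemia_profile(), pan, example_patient()),
               class = "ahpdx_unit_mismatch")
  # units compare case-insensitively
  pan$analytes$units[pan$analytes$name == "HDL"] <- "MG/DL"
  expect_silent(activation_map(hyperglycemia_profile(), pan, example_patient()))
})

test_that("activation is independent of analyte order in the panel", {
  prof <- hyperglycemia_profile()
  pan <- example_panel()
  shuffled <- pan
  shuffled$analytes <- pan$analytes[c(3, 1, 2), ]
  a1 <- activation_map(prof, pan, example_patient())
  a2 <- activation_map(prof, shuffled, example_patient())
  expect_equal(a1$active, a2$active)
  expect_equal(a1$factor_id, a2$factor_id)
})

test_that("demographic age activates against its range at the collection date", {
  prof <- hyperglycemia_profile()
  old <- patient("P002", "male", "1940-01-01")
  pan <- example_panel()
  pan$patient_id <- "P002"
  act <- activation_map(prof, pan, old)
  expect_true(act$active[act$factor_id == "Age"])
  expect_equal(age_at("1977-06-02", "2013-02-15"), 35L)
  expect_equal(age_at("1977-06-02", "2013-06-01"), 35L)
  expect_equal(age_at("1977-06-02", "2013-06-02"), 36L)
})

test_that("clinical observations activate from the panel's observations block", {
  prof <- condition_profile(
    "demo", list(
      risk_factor("A1", category = "elementary", source = "lab_analyte"),
      risk_factor("fatigue", category = "secondary", source = "clinical_observation")
    ),
    weights = c(0.6, 0.4),
    ranges = list(reference_range("A1", high = 10)),
    diagnosis_threshold = 50, critical_threshold = 95
  )
  pat <- patient("P9", "female", "1980-01-01")
  pan <- lab_panel("P9", "2013-01-01",
                   analytes = data.frame(name = "A1", value = 5, units = ""),
                   observations = data.frame(name = "fatigue", present = TRUE))
  act <- activation_map(prof, pan, pat)
  expect_true(act$active[act$factor_id == "fatigue"])
  expect_false(act$active[act$factor_id == "A1"])
})

test_that("profile constructors enforce their invariants", {
  expect_error(risk_factor("x", category = "elementary", source = "demographic"),
               class = "ahpdx_invalid_profile")
  expect_error(reference_range("x"), class = "ahpdx_invalid_profile")
  expect_error(reference_range("x", low = 5, high = 2),
               class = "ahpdx_invalid_profile")
  expect_error(hyperglycemia_profile(diagnosis_threshold = 96,
                                     critical_threshold = 95),
               class = "ahpdx_invalid_profile")
})

test_that("the shipped hyperglycemia config matches the in-code fixture", {
  prof <- read_profile(system.file("extdata", "hyperglycemia.yaml",
                                   package = "ahpdx"))
  expect_equal(prof$condition, "hyperglycemia")
  expect_equal(vapply(prof$factors, `[[`, "", "id"), table1_factors)
  expect_equal(prof$diagnosis_threshold, 80)
  expect_equal(profile_weights(prof)$weights,
               profile_weights(hyperglycemia_profile())$weights)
})
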