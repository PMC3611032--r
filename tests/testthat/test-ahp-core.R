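test_that("the Saaty scale has exactly five odd levels with distinct labels", {
  lv <- saaty_levels()
  expect_equal(lv$value, c(1L, 3L, 5L, 7L, 9L))
  expect_equal(anyDuplicated(lv$label), 0L)
  expect_true(all(1 / lv$value > 0))
})

test_that("required comparison count follows n(n-1)/2", {
  expect_identical(required_comparisons(4), 6L)
  expect_identical(required_comparisons(2), 1L)
  expect_identical(required_comparisons(10), 45L)
  expect_error(required_comparisons(1), class = "ahpdx_invalid_profile")
  expect_error(required_comparisons(2.5), class = "ahpdx_invalid_profile")
})

test_that("build_matrix reproduces the four-factor comparison matrix", {
  m <- table1_matrix()
  expect_equal(unname(m["HDL", ]), c(1, 3, 7, 7))
  expect_equal(unname(m["LDL", ]), c(1 / 3, 1, 5, 5))
  expect_equal(unname(m["Triglyceridea", ]), c(1 / 7, 1 / 5, 1, 1))
  expect_equal(unname(m["Age", ]), c(1 / 7, 1 / 5, 1, 1))
  expect_silent(validate_pairwise(m))
})

test_that("build_matrix accepts p/q ratio strings", {
  m <- build_matrix(c("A", "B"), list(list("A", "B", "7/1")))
  expect_equal(m["A", "B"], 7)
  expect_equal(m["B", "A"], 1 / 7)
})

test_that("build_matrix rejects malformed judgment sets with named pairs", {
  err <- expect_error(
    build_matrix(c("A", "B", "C"), list(list("A", "B", 3))),
    class = "ahpdx_incomplete_judgments"
  )
  expect_match(conditionMessage(err), "\\(A, C\\)")
  expect_match(conditionMessage(err), "\\(B, C\\)")
  expect_error(
    build_matrix(c("A", "B"), list(list("A", "B", 3), list("B", "A", 5))),
    class = "ahpdx_duplicate_judgment"
  )
  expect_error(
    build_matrix(c("A", "B"), list(list("A", "B", -2))),
    class = "ahpdx_invalid_ratio"
  )
})

test_that("non-Saaty ratios are accepted with a warning", {
  expect_warning(m <- build_matrix(c("A", "B"), list(list("A", "B", 4))),
                 "Saaty")
  expect_equal(m["A", "B"], 4)
})

test_that("matrices from random judgments satisfy reciprocity and unit diagonal", {
  set.seed(11)
  for (n in c(3, 4, 5, 7)) {
    factors <- paste0("f", seq_len(n))
    m <- build_matrix(factors, random_judgments(factors))
    expect_silent(validate_pairwise(m))
    expect_equal(max(abs(m * t(m) - 1)), 0, tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, n))
  }
})

test_that("square-and-normalize iteration converges to the known priorities", {
  w <- principal_weights(table1_matrix(), tol = 1e-6)
  expect_true(w$converged)
  expect_equal(w$factors, table1_factors)
  expect_equal(w$weights, table2_weights, tolerance = 5e-4)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
})

test_that("a consistent 2x2 matrix yields its exact eigenvector", {
  m <- build_matrix(c("A", "B"), list(list("A", "B", 3)))
  w <- principal_weights(m)
  expect_equal(w$weights, c(0.75, 0.25), tolerance = 1e-9)
})

test_that("consistent matrices built from known weights are recovered exactly", {
  for (target in list(c(0.5, 0.3, 0.2), c(0.4, 0.3, 0.2, 0.1),
                      c(0.7, 0.1, 0.1, 0.05, 0.05))) {
    w <- principal_weights(consistent_matrix(target))
    expect_equal(w$weights, target, tolerance = 1e-9)
  }
})

test_that("squaring iteration matches the generic dominant-eigenvector oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    factors <- paste0("f", seq_len(n))
    m <- build_matrix(factors, random_judgments(factors))
    got <- principal_weights(m, tol = 1e-9, max_iter = 30)$weights
    expect_equal(got, dominant_eigvec(m), tolerance = 1e-6)
  }
})

test_that("weights are invariant under simultaneous factor permutation", {
  set.seed(21)
  factors <- paste0("f", 1:5)
  m <- build_matrix(factors, random_judgments(factors))
  perm <- sample(5)
  mp <- structure(unclass(m)[perm, perm], class = class(m))
  w <- principal_weights(m)$weights
  wp <- principal_weights(mp)$weights
  expect_equal(wp, w[perm], tolerance = 1e-9)
})

test_that("non-convergence within max_iter is reported, not raised", {
  w <- principal_weights(table1_matrix(), tol = 1e-12, max_iter = 1)
  expect_false(w$converged)
  expect_identical(w$iterations_used, 1L)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
})

test_that("percentage view uses largest-remainder rounding to a sum of 100", {
  w <- principal_weights(table1_matrix())
  pct <- to_percentages(w)
  expect_identical(unname(pct), c(58L, 28L, 7L, 7L))
  expect_identical(sum(pct), 100L)
  expect_identical(unname(to_percentages(rep(0.25, 4))), rep(25L, 4))
  expect_identical(unname(to_percentages(1)), 100L)
})

test_that("percentages always sum to 100 and sit within 1 of the exact value", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    w <- runif(n); w <- w / sum(w)
    pct <- to_percentages(w)
    expect_identical(sum(pct), 100L)
    expect_true(all(abs(pct - 100 * w) < 1))
  }
})

test_that("consistency ratio is zero for consistent matrices and small here", {
  expect_equal(consistency_ratio(consistent_matrix(c(0.5, 0.3, 0.2))), 0,
               tolerance = 1e-6)
  cr <- consistency_ratio(table1_matrix())
  expect_gt(cr, 0)
  expect_lt(cr, 0.10)
  m2 <- build_matrix(c("A", "B"), list(list("A", "B", 3)))
  expect_error(consistency_ratio(m2), class = "ahpdx_unsupported_size")
})
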