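#' The five-level Saaty importance scale
#'
#' Pairwise judgments are expressed on Saaty's fundamental scale: five odd
#' integer levels from equal (1) to extreme (9) importance. The reciprocal of
#' each level expresses the inverse judgment.
#'
#' @return A data frame with columns `value` (integer) and `label`
#'   (character), one row per level, in increasing order of importance.
#' @examples
#' saaty_levels()
#' @export
saaty_levels <- function() {
  data.frame(
    value = c(1L, 3L, 5L, 7L, 9L),
    label = c("Equal Importance", "Moderate Importance", "Strong Importance",
              "Very Strong Importance", "Extreme Importance"),
    stringsAsFactors = FALSE
  )
}

#' Number of pairwise comparisons required for n factors
#'
#' Every unordered pair of risk factors must be judged once, so a full set of
#' judgments has `n * (n - 1) / 2` entries.
#'
#' @param n_factors Number of risk factors; must be at least 2.
#' @return Integer count of required comparisons.
#' @examples
#' required_comparisons(4) # 6
#' @export
required_comparisons <- function(n_factors) {
  if (!is.numeric(n_factors) || length(n_factors) != 1L ||
      is.na(n_factors) || n_factors != round(n_factors) || n_factors < 2) {
    stop_ahpdx("invalid_profile",
               "n_factors must be a single integer >= 2, got ",
               deparse(substitute(n_factors)), " = ",
               paste(format(n_factors), collapse = ", "))
  }
  as.integer(n_factors * (n_factors - 1) / 2)
}

# Parse a judgment ratio given as a number or a "p/q" string ("7/1", "1/3").
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    x <- trimws(x)
    if (grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", x)) {
      parts <- as.numeric(strsplit(x, "/")[[1]])
      if (parts[2] == 0) stop_ahpdx("invalid_ratio", "zero denominator in ratio '", x, "'")
      return(parts[1] / parts[2])
    }
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) return(num)
  }
  stop_ahpdx("invalid_ratio", "cannot parse ratio: ", deparse(x))
}

saaty_ratio_ok <- function(r) {
  lv <- saaty_levels()$value
  any(abs(r - lv) < 1e-9) || any(abs(r - 1 / lv) < 1e-9)
}

#' Build a pairwise comparison matrix from judgments
#'
#' Assembles the reciprocal comparison matrix from one judgment per unordered
#' factor pair. A judgment `(i, j, r)` states that factor `i` is `r` times as
#' important as factor `j`; the diagonal is 1 and `a[j,i] = 1/r` is filled in
#' automatically. Ratios may be numbers or `"p/q"` strings. Values outside the
#' five Saaty levels and their reciprocals (e.g. the intermediate levels 2, 4,
#' 6, 8) are accepted with a warning.
#'
#' @param factors Character vector of at least two unique factor identifiers;
#'   fixes row/column order.
#' @param judgments A list of length-3 entries `(factor_i, factor_j, ratio)`,
#'   or a data frame with columns `i`, `j`, `ratio`.
#' @return A `pairwise_matrix`: a numeric matrix with factor dimnames, unit
#'   diagonal and exact reciprocal symmetry.
#' @examples
#' m <- build_matrix(c("A", "B"), list(list("A", "B", 3)))
#' m["B", "A"] # 1/3
#' @export
build_matrix <- function(factors, judgments) {
  factors <- as.character(factors)
  n <- length(factors)
  if (n < 2L) stop_ahpdx("invalid_profile", "need at least 2 factors")
  if (anyDuplicated(factors)) stop_ahpdx("invalid_profile", "duplicate factor ids")
  if (is.data.frame(judgments)) {
    judgments <- lapply(seq_len(nrow(judgments)), function(k)
      list(judgments[[1]][k], judgments[[2]][k], judgments[[3]][k]))
  }

  m <- diag(n)
  dimnames(m) <- list(factors, factors)
  seen <- matrix(FALSE, n, n)
  for (jd in judgments) {
    if (length(jd) != 3L) stop_ahpdx("invalid_ratio", "judgment must be (i, j, ratio)")
    i <- match(as.character(jd[[1]]), factors)
    j <- match(as.character(jd[[2]]), factors)
    if (is.na(i) || is.na(j)) {
      stop_ahpdx("invalid_profile", "judgment names unknown factor: ",
                 jd[[1]], " vs ", jd[[2]])
    }
    if (i == j) stop_ahpdx("invalid_ratio", "self-comparison for factor ", factors[i])
    r <- parse_ratio(jd[[3]])
    if (!is.finite(r) || r <= 0) {
      stop_ahpdx("invalid_ratio", "ratio for (", factors[i], ", ", factors[j],
                 ") must be a positive number, got ", format(r))
    }
    lo <- min(i, j); hi <- max(i, j)
    if (seen[lo, hi]) {
      stop_ahpdx("duplicate_judgment", "pair (", factors[lo], ", ", factors[hi],
                 ") judged more than once")
    }
    seen[lo, hi] <- TRUE
    if (!saaty_ratio_ok(r)) {
      warning("ratio ", format(r), " for (", factors[i], ", ", factors[j],
              ") is not one of the five Saaty levels or their reciprocals",
              call. = FALSE)
    }
    m[i, j] <- r
    m[j, i] <- 1 / r
  }

  missing <- which(upper.tri(m) & !seen, arr.ind = TRUE)
  if (nrow(missing) > 0L) {
    pairs <- apply(missing, 1L, function(ij)
      paste0("(", factors[ij[1]], ", ", factors[ij[2]], ")"))
    stop_ahpdx("incomplete_judgments",
               "missing judgments for pairs: ", paste(pairs, collapse = ", "))
  }
  structure(m, class = c("pairwise_matrix", "matrix", "array"))
}

#' Validate pairwise-matrix invariants
#'
#' Checks unit diagonal, strict positivity and reciprocal symmetry
#' (`a[j,i] * a[i,j] == 1` within relative tolerance 1e-9).
#'
#' @param m A square numeric matrix.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_pairwise <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L) {
    stop_ahpdx("invalid_profile", "pairwise matrix must be square, n >= 2")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop_ahpdx("invalid_ratio", "pairwise matrix entries must be finite and positive")
  }
  if (any(abs(diag(m) - 1) > 1e-9)) {
    stop_ahpdx("invalid_ratio", "pairwise matrix diagonal must be 1")
  }
  rec <- abs(m * t(m) - 1)
  if (any(rec > 1e-9)) {
    stop_ahpdx("invalid_ratio", "reciprocity violated: max |a_ij * a_ji - 1| = ",
               format(max(rec)))
  }
  invisible(m)
}

#' Priority weights by iterated matrix squaring
#'
#' Derives the principal (priority) weight vector of a pairwise comparison
#' matrix by repeatedly squaring the matrix, summing its rows and normalizing
#' the row sums to 1. Each squaring doubles the effective matrix power, so the
#' normalized row sums converge to the dominant eigenvector very quickly. The
#' iteration stops when the maximum absolute per-component change between
#' successive normalized vectors falls below `tol`, or after `max_iter`
#' squarings. To keep entries bounded, the running matrix is divided by its
#' largest entry before each squaring; row-sum normalization makes the result
#' invariant to this rescaling.
#'
#' @param matrix A `pairwise_matrix` (or any valid reciprocal matrix).
#' @param tol Convergence tolerance on the weight vector; default `1e-6`.
#' @param max_iter Maximum number of squarings; default 20.
#' @return A `weight_vector`: list with `factors`, `weights` (non-negative,
#'   summing to 1, in factor order), `iterations_used` and `converged`.
#' @examples
#' m <- build_matrix(c("A", "B"), list(list("A", "B", 3)))
#' principal_weights(m)$weights # 0.75 0.25
#' @export
principal_weights <- function(matrix, tol = 1e-6, max_iter = 20L) {
  validate_pairwise(matrix)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop_ahpdx("invalid_profile", "tol must be a positive number")
  }
  if (max_iter < 1L) stop_ahpdx("invalid_profile", "max_iter must be >= 1")
  factors <- rownames(matrix)
  if (is.null(factors)) factors <- paste0("f", seq_len(nrow(matrix)))

  m <- unclass(matrix)
  w_prev <- NULL
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(max_iter)) {
    m <- m / max(m)   # overflow guard; scale-invariant under row normalization
    m <- m %*% m
    if (any(!is.finite(m))) {
      stop_ahpdx("numeric_failure", "non-finite entries during matrix squaring")
    }
    w <- rowSums(m)
    w <- w / sum(w)
    iters <- k
    if (!is.null(w_prev) && max(abs(w - w_prev)) < tol) {
      converged <- TRUE
      break
    }
    w_prev <- w
  }
  structure(
    list(factors = factors, weights = as.numeric(w),
         iterations_used = iters, converged = converged),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("AHP priority weights (", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations_used, " squarings)\n", sep = "")
  for (i in seq_along(x$factors)) {
    cat(sprintf("  %-16s %.6f\n", x$factors[i], x$weights[i]))
  }
  invisible(x)
}

#' Integer-percentage view of a weight vector
#'
#' Converts fractional weights to integer percentages that sum exactly to 100
#' using largest-remainder rounding: each weight is floored at `100 * w`, and
#' the leftover points go to the largest fractional remainders, ties broken by
#' factor order.
#'
#' @param weights A `weight_vector`, or a bare numeric vector summing to 1.
#' @return A named integer vector of percentages summing to 100.
#' @examples
#' to_percentages(c(HDL = 0.582726, LDL = 0.282482, Tri = 0.067396, Age = 0.067396))
#' @export
to_percentages <- function(weights) {
  if (inherits(weights, "weight_vector")) {
    w <- weights$weights
    names(w) <- weights$factors
  } else {
    w <- as.numeric(weights)
    names(w) <- names(weights)
  }
  if (any(!is.finite(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_ahpdx("invalid_profile",
               "weights must be non-negative and sum to 1 (got sum ", format(sum(w)), ")")
  }
  p <- 100 * w
  fl <- floor(p)
  leftover <- 100L - as.integer(round(sum(fl)))
  if (leftover > 0L) {
    # stable order: largest remainder first, earlier factor wins ties
    take <- order(-(p - fl), seq_along(p))[seq_len(leftover)]
    fl[take] <- fl[take] + 1
  }
  stats::setNames(as.integer(fl), names(w))
}

# Saaty's random consistency index for n = 3..10.
RANDOM_INDEX <- c(`3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
                  `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49)

#' Consistency ratio of a pairwise comparison matrix
#'
#' Standard AHP diagnostic: estimates the principal eigenvalue
#' \eqn{\lambda_{max}} as the mean of `(A w) / w` over the converged weights
#' `w`, then compares the consistency index
#' \eqn{(\lambda_{max} - n) / (n - 1)} with Saaty's random index `RI(n)`.
#' A perfectly consistent matrix has ratio 0; ratios below 0.10 are
#' conventionally acceptable.
#'
#' @param matrix A `pairwise_matrix` with 3 to 10 factors (the range the
#'   random-index table covers).
#' @return Non-negative consistency ratio.
#' @export
consistency_ratio <- function(matrix) {
  validate_pairwise(matrix)
  n <- nrow(matrix)
  if (n < 3L || n > 10L) {
    stop_ahpdx("unsupported_size",
               "consistency ratio is defined here for 3 <= n <= 10, got n = ", n)
  }
  w <- principal_weights(matrix)$weights
  lambda_max <- mean((unclass(matrix) %*% w) / w)
  cr <- (lambda_max - n) / ((n - 1) * RANDOM_INDEX[[as.character(n)]])
  max(cr, 0)
}
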