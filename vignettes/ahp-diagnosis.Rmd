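---
title: "AHP-weighted diagnosis from laboratory panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AHP-weighted diagnosis from laboratory panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpdx)
```

## The model

`ahpdx` scores a patient for a condition in three steps.

**1. Priority weights from pairwise judgments.** A condition profile lists
$n$ risk factors and one judgment per unordered pair on the five-level
Saaty scale ($1, 3, 5, 7, 9$; intermediates $2, 4, 6, 8$ are accepted with
a warning since standard AHP admits them). Judgment $(i, j, r)$ means
factor $i$ is $r$ times as important as factor $j$; the comparison matrix
gets $a_{ij} = r$, $a_{ji} = 1/r$, $a_{ii} = 1$. The priority vector is the
normalized dominant eigenvector of this matrix. `principal_weights()`
computes it by iterated squaring: repeatedly square the running matrix,
take row sums, and normalize them to sum 1. Powers of a positive matrix
align their rows with the dominant eigenvector (the Perron vector), and
squaring doubles the exponent each pass, so convergence is geometric with a
doubling exponent — the four-factor example below converges in four
squarings.

**2. Reference-range activation.** Each elementary factor is compared with
the reference range resolved for the patient's sex and age; a factor
*activates* when the value lies strictly beyond a bound. Demographic
factors (age at the panel's collection date) and clinical observations
(explicit booleans in the panel) activate the same way.

**3. Weighted-sum score and thresholds.** The score is $100$ times the
summed weight of active factors. Classification is positive when the score
reaches the profile's `diagnosis_threshold`; at `critical_threshold` the
result additionally carries a critical notification event.

```{r}
m <- build_matrix(
  c("HDL", "LDL", "Triglyceridea", "Age"),
  list(list("HDL", "LDL", 3), list("HDL", "Triglyceridea", 7),
       list("HDL", "Age", 7), list("LDL", "Triglyceridea", 5),
       list("LDL", "Age", 5), list("Triglyceridea", "Age", 1)))
principal_weights(m)
consistency_ratio(m)
```

## Assumptions and their consequences

The engine is deliberately rule-based, not probabilistic. Its core
assumptions:

- *Binary activation*: a factor contributes its full weight once out of
  range, regardless of how far out. A value of 41 and 400 mg/dL against an
  upper bound of 40 contribute identically. This keeps the score
  interpretable as "percentage of diagnostic evidence present" but discards
  severity information.
- *Additivity*: factor contributions sum; no interactions between analytes
  are modelled.
- *Judgment quality*: weights are only as good as the physician's pairwise
  judgments. `consistency_ratio()` flags incoherent judgment sets
  (conventionally, ratios above 0.10 warrant re-elicitation).

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tol` (`principal_weights`) | 1e-6 | — | max per-component change between successive normalized vectors at which iteration stops |
| `max_iter` | 20 | squarings | hard stop; each squaring doubles the matrix power, so 20 is far beyond practical need |
| `diagnosis_threshold` | 80 | % | score at or above which the classification is positive |
| `critical_threshold` | 95 | % | score at or above which a critical event is raised; must be ≥ the diagnosis threshold |
| `margin` (`cohort_spec`) | 0.10 | fraction of bound | how far beyond a bound the generator forces out-of-range values |

The 80% default positivity threshold is the system default a physician is
expected to override per condition. It is a *threshold*, not an expected
score: in the worked hyperglycemia example the two activated factors sum to
86.52%, which clears the threshold. Threshold comparison is inclusive
(score = threshold is positive) and activation is strict (value = bound is
in range); both boundary conventions are fixed here because the natural
reading of "over 40 / lower than 80" is strict, and an inclusive threshold
lets a physician state "at 80% I want to be told" directly.

## Numerical choices

- The running matrix is divided by its largest entry before each squaring.
  Entries of matrix powers grow geometrically and would overflow double
  precision after a few dozen squarings; row-sum normalization makes the
  weights invariant to this rescaling.
- Convergence is measured on the *normalized* vector (max absolute
  per-component change), so `tol` is a tolerance on the weights themselves.
- Non-convergence within `max_iter` is reported via the `converged` flag
  rather than an error: the caller decides whether a partially converged
  vector is usable.
- Integer percentages use largest-remainder rounding (floor everything,
  hand the leftover points to the largest fractional remainders, ties to
  the earlier factor). This is the only integer rounding that both
  preserves the exact 100 total and keeps every percentage within one point
  of `100 * w`. Scores are always computed from unrounded weights; the
  integer view is presentation only, so display rounding can never flip a
  classification.
- `λ_max` for the consistency ratio is estimated as the mean of
  `(A w) / w` over the converged weights — exact for consistent matrices
  and standard practice otherwise. The random-index table covers
  `n = 3..10`; outside that the ratio is refused.

## Reference-range resolution

Ranges may be stratified by sex and age. `resolve_range()` picks the most
specific match: a range declared for the patient's exact sex beats
`sex = "any"`, and among equally sex-specific candidates the narrowest age
span wins; remaining ties go to the earlier range, so resolution is
deterministic. Age is computed from the birth date *at the panel's
collection date*, not at call time, so a stored diagnosis never drifts.
Units are compared as case-insensitive strings with no conversion — a
mismatch is an error, not a silent reinterpretation. Factors absent from a
panel count as inactive but are reported as unobserved, so a diagnosis on
an incomplete panel is visibly incomplete rather than silently optimistic.

## The shipped hyperglycemia profile

The four-factor example encodes: HDL active above its sex-specific upper
bound (40 mg/dL male, 50 mg/dL female), LDL active below 80 mg/dL,
triglycerides in 40–150 mg/dL, and age active above 60 years. The two
bounds that drive the worked example (HDL male 40, LDL 80) are fixed by the
example itself; the female HDL bound, triglyceride interval and age bound
are this package's choices of clinically ordinary values, picked once so
that the worked-example patient (male, 35, triglycerides 120) activates
exactly HDL and LDL. The activation *directions* (HDL high = risk, LDL
low = risk) are the profile's statement, encoded as given; profile authors
own clinical correctness.

## The synthetic cohort generator

`generate_cohort()` is the package's test bed: no external data exist for
this engine, so cohorts with controlled ground truth are generated.
Prevalence is applied as an exact count (`round(n * prevalence)` patients
receive the positive recipe), not Bernoulli draws, so cohort composition is
deterministic and tests are sharp. Negative records sample every analyte
strictly inside the range resolved for the generated patient (uniformly,
inset 1% from each end); positives take the recipe factors to
`bound * (1 ± margin)`, default margin 10%, well clear of the strict
activation boundary. Ages are sampled uniformly on 25–45 years by default,
which must lie inside any demographic factor's range for negatives to stay
clean. The generator refuses recipes whose combined weight cannot reach the
diagnosis threshold (such "positives" would be undetectable by
construction) unless that regime is requested explicitly.

What the generator does *not* emulate: analyte–analyte correlation,
measurement error, missingness patterns, or borderline values. A perfect
confusion matrix on these cohorts therefore demonstrates that the pipeline
(generation → XML serialization → parsing → activation → scoring →
classification) is faithful, not that the method separates real patients.

Default evaluation size is 100 patients at 20% prevalence under a fixed
seed — large enough to exercise both classes and both sexes, small enough
that the full suite runs in seconds.

## Known limitations

- Weight elicitation supports a single physician's judgments; aggregating
  several judgment matrices (group AHP) and fuzzy extensions are out of
  scope.
- No unit conversion or terminology coding (LOINC); analyte matching is by
  exact id.
- The record store is a single-writer, line-delimited file — a storage
  contract, not a database.
- RSS items deliberately carry no clinical numbers: feeds are an
  unauthenticated channel, so details stay behind the store.
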