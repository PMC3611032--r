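# ahpdx

Clinical decision support for lab-test-based screening, built on the
Analytic Hierarchy Process (AHP). `ahpdx` is aimed at medical-informatics
developers and physicians who want a transparent, configurable rule engine:
the physician states *pairwise* how much each risk factor matters for a
condition, the package turns those judgments into priority weights, and a
patient's diagnosis score is simply the summed weight of every factor whose
lab value lies outside its reference range.

## The method

For a condition with risk factors \(f_1, \dots, f_n\) (lab analytes such as
HDL or LDL, plus demographics such as age), the physician supplies one
judgment per unordered pair on Saaty's five-level scale (1 equal, 3
moderate, 5 strong, 7 very strong, 9 extreme importance) — \(n(n-1)/2\)
judgments in all. These fill a positive reciprocal matrix \(A\) with
\(a_{ii} = 1\) and \(a_{ji} = 1/a_{ij}\). The priority weight vector **w**
is the normalized dominant eigenvector of \(A\), computed here by the
classical squaring iteration: square the matrix, sum its rows, normalize to
1, and repeat until the vector stops changing (each squaring doubles the
effective power of the matrix, so a handful of iterations suffices).

A factor *activates* when the patient's value is strictly beyond its
(sex- and age-specific) reference range. The diagnosis score is
\(100 \sum_{i \in \text{active}} w_i\); the classification is positive when
the score reaches the profile's diagnosis threshold (system default 80%,
physician-configurable), and cases at or above the critical threshold
(default 95%) additionally raise an immediate notification event. The
standard AHP consistency ratio is available as a diagnostic on the
physician's judgments (`consistency_ratio()`, acceptable below 0.10).

Around the engine the package provides the supporting data flow: an XML
dialect for uploaded lab panels, a single-file keyed record store with
chronological retrieval, RSS 2.0 notification feeds, a synthetic-cohort
generator with known ground truth, and the `ahpdx` command-line tool
(`exec/ahpdx`).

## Worked example

The shipped hyperglycemia profile has four risk factors. Deriving its
weights:

```r
library(ahpdx)
prof <- read_profile(system.file("extdata", "hyperglycemia.yaml", package = "ahpdx"))
profile_weights(prof)
#> AHP priority weights (converged in 4 squarings)
#>   HDL              0.582726
#>   LDL              0.282482
#>   Triglyceridea    0.067396
#>   Age              0.067396
to_percentages(profile_weights(prof))
#>           HDL           LDL Triglyceridea           Age
#>            58            28             7             7
```

HDL carries 58% of the diagnostic weight, LDL 28%, and the remaining two
factors 7% each (largest-remainder rounding, so the integers always total
100). Diagnosing a 35-year-old male whose HDL is 45 mg/dL (above his
40 mg/dL bound) and LDL 70 mg/dL (below the 80 mg/dL bound):

```r
pat <- patient("P001", "male", "1977-06-02")
pan <- parse_panel_xml(system.file("extdata", "panel-example.xml", package = "ahpdx"))
diagnose(prof, pat, pan)
#> Diagnosis: hyperglycemia | patient P001 | panel 2013-02-15
#>   HDL               58%  ACTIVE
#>   LDL               28%  ACTIVE
#>   Triglyceridea      7%  in range
#>   Age                7%  in range
#>   score 86.52% -> positive
```

Two factors are out of range, their weights sum to 86.52%, and that clears
the 80% positivity threshold. The same pipeline is scriptable:
`ahpdx diagnose --profile ... --patient ... --panel ...` exits 0 for a
negative, 2 for a positive and 3 for a critical case.

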