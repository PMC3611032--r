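Package: ahpdx
Title: Analytic Hierarchy Process Weighting for Automated Lab-Test Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinical decision support built on the Analytic Hierarchy
    Process (AHP): derives priority weights for illness risk factors from
    Saaty-scale pairwise comparison matrices by iterated matrix squaring,
    activates factors whose lab values lie beyond sex- and age-specific
    reference ranges, and sums activated weights into a percentage diagnosis
    score with configurable positivity and critical thresholds. Includes an
    XML dialect for laboratory panels, a line-delimited record store with
    chronological retrieval, RSS 2.0 notification feeds, a synthetic-cohort
    generator for end-to-end evaluation, and an 'ahpdx' command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
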