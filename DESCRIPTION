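Package: actisleep
Title: Immobility-Defined Sleep, Circadian Rhythm and Family-Variant
    Analysis for Behavioural Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for passive-infrared actigraphy and related
    phenotyping data: immobility-based sleep scoring (40-s rule on 10-s
    activity bins), activity/sleep bout segmentation and length
    categorisation, chi-square periodogram rhythm analysis with
    free-running period (tau) estimation under multiple lighting
    conditions, double-plotted actograms, repeated-measures ANOVA with
    Bonferroni post-hoc comparisons, family-quartet inheritance-model
    variant filtering from annotated VCFs, and three-parameter
    dose-response (EC50) fitting.  Includes synthetic-data generators for
    every input kind (mouse activity cohorts, ultra-long human sleep
    diaries, pedigree VCFs with planted candidate variants, and agonist
    dose-response tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
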