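Package: sexspec
Title: Sex-Specific Exposure Effects in Omics Profiles via Significance-Rank Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sex-specific effects of an exposure (tobacco smoking) on
    genome-wide expression and DNA-methylation features using a rank-based,
    non-parametric procedure. Candidate features associated with the exposure
    in a mixed-sex analysis are re-ranked by significance in sex-stratified
    analyses; the difference of the male and female ranks is tested against a
    Gaussian null fitted to the candidate set, with the survival function
    providing per-feature tail probabilities. Includes a synthetic-cohort
    generator emulating a two-cohort blood-leukocyte study design, a balanced
    female-resampling robustness check, effect-size summaries (expression
    ratios and methylation delta-beta), and curated fixtures of the published
    sex-specific result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
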