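Package: pregcohort
Title: Cohort Construction for Drug Safety in Pregnancy from Timestamped Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds observational pregnancy cohorts from a corpus of timestamped
    user posts. Detects beta-blocker mentions via a keyword/misspelling lexicon,
    classifies self-reported medication intake with transparent first-person
    pattern rules, estimates 280-day prenatal windows from pregnancy anchors
    (due-date countdowns, weeks-pregnant statements and hashtags), classifies
    per-pregnancy drug exposure (explicit, timestamp-inferred, possible, or not
    during pregnancy), extracts adverse and normal pregnancy outcomes (preterm
    birth, NICU admission, low birth weight, birth defects, miscarriage,
    stillbirth; term gestational age and normal birth weight for reporting-bias
    assessment) and covariates (maternal age, indication for use), and assembles
    per-pregnancy cohort records with summary tables. Includes a synthetic
    post-corpus generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
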