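Package: tp53ea
Title: TP53 Mutation Classification and Prognostic Stratification for NSCLC Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based functional classification of TP53 protein variants
    (missense versus truncating, exon location, disruptive versus nondisruptive
    by the L2/L3-loop polarity/charge rule, and evolutionary-action EAp53
    high/low risk), patient-level aggregation and stratification of
    non-small cell lung cancer cohorts, Kaplan-Meier / log-rank / Cox
    proportional-hazards survival comparison across the resulting strata,
    and genomic-landscape, pathway and tumor-mutation-burden contrasts
    between EAp53 high-risk patients and all others.  A seeded synthetic
    cohort generator reproduces the statistical structure the analyses
    assume, so the entire pipeline runs and is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
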