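Package: speechscreen
Title: Linguistic-Feature Screening of Cognitive Impairment from Speech Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screening Alzheimer's disease and related
    dementias (ADRD) from picture-description speech transcripts. Extracts an
    interpretable 100-dimensional linguistic feature vector (lexical diversity
    indices, dictionary-based psycholinguistic category proportions, an
    analytic-thinking composite and a disfluency aggregate), trains Random
    Forest models for ADRD detection and MMSE severity regression with
    cross-validation and bootstrap evaluation, stratifies predicted risk into
    a Green/Amber/Red traffic-light triage scheme via Youden's J threshold
    search, and reports calibration, feature attributions, subgroup performance
    and demographic parity. Ships a synthetic cohort generator so the full
    pipeline is testable without access-restricted clinical speech data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
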