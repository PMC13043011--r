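Package: CheckinBiomarkers
Title: Multimodal Digital Biomarkers from Conversational Check-In Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts a 66-feature library of visual (facial landmark and
    blendshape), acoustic (voice), and linguistic (transcript) digital
    biomarkers from conversational check-in sessions, and implements the
    accompanying statistical stage: baseline (earliest-session) selection,
    per-feature outlier removal, Pearson correlation of each feature against
    depression, fatigue and cognition instruments (PHQ-9, Cancer Fatigue
    Scale, Trail Making Test), and a within-person composite risk score for
    longitudinal monitoring. Includes a fully deterministic synthetic-cohort
    generator (source-filter speech synthesis, blendshape streams, timed
    transcripts) with sign-controlled feature-symptom couplings so the whole
    pipeline is testable without access to operational data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
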