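Package: hubreserve
Title: Left Frontal Hub Connectivity and Cognitive Reserve in Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying cognitive reserve through global
    hub connectivity of the left frontal cortex in resting-state fMRI.
    Computes a global connectivity score (mean positive Fisher-z correlation
    between an 8 mm seed sphere and all grey-matter voxels) from denoised,
    motion-scrubbed 4D runs; fits moderation (disease severity x connectivity)
    linear mixed models of cognition with AIC-based full-versus-reduced
    comparison; fits polynomial mixed-effects trajectory models over estimated
    years to symptom onset or CSF tau and derives standardized between-group
    difference curves; and generates seedable synthetic BOLD runs and
    DIAN-like / DELCODE-like cohort tables with planted effects so the whole
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
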