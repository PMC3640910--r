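Package: agnortools
Title: AgNOR Morphometry and Survival Analysis for Histological Nucleus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies silver-stained nucleolar organizer regions (AgNORs) inside
    manually marked tumour-cell nuclei and relates the resulting morphometric
    profile to patient survival. Provides a seeded synthetic generator for nucleus
    images with known AgNOR ground truth and for survival cohorts with known hazard
    structure; per-nucleus dark-dot detection with an area-ratio conglomerate
    correction; the case-level AgNOR feature vector (mean corrected count,
    count-class percentages, area-fraction and positional dispersion statistics);
    and Kaplan-Meier estimation, Cox proportional-hazards fitting, backward
    stepwise likelihood-ratio model selection and SPSS-style case-processing
    summaries for overall and cause-specific endpoints, plus an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
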