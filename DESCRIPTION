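Package: rhythmpower
Title: Population-Mean Cosinor Rhythm Screening and Statistical Power Under
    Rhythmic Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects 24-hour (circadian) and 12-hour (ultradian) rhythms in
    multi-participant protein time series using per-individual single-component
    cosinor fits summarised by the population-mean cosinor with a Hotelling-type
    zero-amplitude test, and quantifies the statistical cost of leaving such
    rhythms uncontrolled in two-group biomarker studies: the inflation of the
    required sample size and the rise in the Type II error rate implied by the
    rhythm's added variance. Includes a synthetic cohort generator emulating a
    constant-routine serum proteomics study (two-hourly sampling across 30
    hours, technical replicates, DLMO-aligned time), preprocessing (replicate
    averaging, missingness filtering, per-participant z-scoring, clock-to-DLMO
    conversion), and a configuration-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
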