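Package: noctiglyc
Title: Nocturnal Sleep Structure and Next-Day Glycemic Control from CGM and Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking wrist-actigraphy sleep staging to
    next-day glycemic control measured by flash continuous glucose monitoring
    (CGM) in adults with type 1 diabetes. Reads FreeStyle Libre-style CGM
    exports and Fitbit-style sleep-stage logs, synchronizes both streams onto
    a common 15-minute grid, and computes per-night sleep metrics (efficiency,
    WASO, awakenings, stage ratios, Shannon entropy, a 2-of-3 quality rule,
    PSQI scoring) and per-day glycemic metrics (time in ranges via Rosendaal
    per-minute interpolation, episode counts, MAGE, MODD-style daily
    differences). Nights are encoded by their stage-transition structure and
    grouped with k-means; cluster-average glucose curves are mined for
    cluster-specific motifs with a PAA/SAX symbolic representation, TF-IDF
    weighting and cosine similarity; clusters are compared with Welch's
    heteroscedastic F-test and Bonferroni-adjusted pairwise tests. A
    synthetic cohort generator with planted sleep archetypes and a tunable
    sleep-glucose coupling makes the whole pipeline testable without device
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
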