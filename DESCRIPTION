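Package: conattract
Title: Conspecific Attraction Analyses: Settlement Point Processes and
    Conditional-Logit Mate Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing conspecific attraction in territorial
    songbirds. Fits loglinear inhomogeneous Poisson point-process models of
    male settlement density against kernel-density habitat-attractiveness
    rasters and exponential distance-decay playback-proximity rasters, using
    a Berman-Turner quadrature approximation fitted jointly across several
    site-year point patterns. Fits a conditional-logit mate-choice model in
    which male attractiveness is a power function of habitat value and a
    metapopulation-style connectivity statistic, and compares candidate
    models by AICc with Akaike weights and model averaging. Includes a
    seeded synthetic-data generator for landscapes, nests, playback arrays,
    settlement patterns and female choice events, plus preprocessing of raw
    territory-observation and nest tables into analysis units.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
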