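Package: beadlysis
Title: Quantitative Analysis of Nanobead-Labeled Fibrin Fiber Lysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how fluorescent nanobead labeling alters
    in vitro fibrinolysis of single fibrin fibers. Provides deterministic
    dosimetry arithmetic (bead stock concentration from solids fraction,
    dilution series, beads per fiber volume, illumination energy dose), a
    2-D lattice random-walk Monte Carlo of bead diffusion with an absorbing
    fiber boundary (binding frequency and binding time by location along the
    fiber), tabulation and statistics of per-fiber lysis outcomes (cleavage
    times, outcome percentages, box-whisker summaries, one-way ANOVA, linear
    regression of percentages against concentration), and a seeded synthetic
    generator of fiber-fate records for end-to-end testing of the analysis
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
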