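Package: focusct
Title: Focused True Discovery Guarantees by Combining Partial Closed Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simultaneous lower confidence bounds for the number (and
    proportion) of true discoveries in arbitrary feature sets, with power
    concentrated on a prespecified family of "focus sets". Partial true
    discovery guarantee procedures on the focus sets (closed testing with
    Fisher combination local tests, or user-supplied bound oracles) are
    combined with Bonferroni or Holm alpha-recycling, extended to post hoc
    query sets by interpolation with an exact small-universe mode and a fast
    greedy shortcut, and verified against the explicit closed testing
    construction. Includes a replicability analysis application: per-feature
    lower bounds on the number of replicating studies via partial conjunction
    closed testing, with AdaFilter as a comparator, plus seeded synthetic data
    generators for the supported simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
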