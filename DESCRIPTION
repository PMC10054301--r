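Package: electromeR
Title: Approximate Entropy Analysis of Fruit Electrome Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the complexity of plant surface electrical
    recordings (the electrome) with approximate entropy (ApEn). Provides an
    exact, verified ApEn implementation (m = 2, r = 0.2 x SD defaults, natural
    log, Chebyshev or Euclidean match norm), readers and writers for
    micro-voltage time series sampled at a fixed rate, a seeded synthetic
    generator of multi-day fruit ripening cohorts whose signal regularity
    varies by ripening stage, sliding-window ApEn profiling with detection of
    the breaker-stage entropy dip, per-stage summaries, and a nearest-centroid
    stage classifier built on windowed signal features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
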