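Package: levymut
Title: Stable Levy Models of Mutation Length Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models mutation accumulation along a cell lineage as a Levy
    flight with two components: single point mutations and large DNA
    rearrangements whose lengths follow a one-sided stable Levy law.
    Provides numerical evaluation and sampling of the stable density and
    its survival function, rank-size (integrated) length distributions
    with power-law and integrated-Levy tail fits, per-generation mutation
    rate estimation from accumulation time series with a mutator
    changepoint, a forward lineage simulator, and generators of
    study-shaped synthetic catalogs and time series with detection
    censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
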