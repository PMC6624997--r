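Package: sparsepeaks
Title: Empirical Signal-Block Peak Calling for Sparse CUT&RUN Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Model-free peak calling for sparse chromatin profiling data such
    as CUT&RUN, where background coverage is dominated by zeros. Adjacent
    nonzero bedgraph intervals are aggregated into signal blocks, an empirical
    threshold on per-block total signal is selected from the joint
    distribution of target and IgG control blocks (stringent and relaxed
    modes, with optional density-peak normalization of the control), and
    blocks exceeding the threshold are reported as peaks together with an
    empirical false discovery rate. Includes overlap-based precision/recall
    and AUPR evaluation against reference peak sets, and a seeded synthetic
    generator of paired target/IgG coverage with known truth for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
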