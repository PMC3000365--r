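Package: cagdyn
Title: Somatic CAG-Repeat Instability from Fragment-Analysis Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of somatic CAG trinucleotide-repeat
    instability from capillary-electrophoresis fragment-analysis traces.
    Decomposes electropherograms into consecutive normal components with a
    masked Nelder-Mead simplex fit, inverts the mean/variance drift
    equations of a daily unitary expansion/contraction random walk,
    quantifies periodic ~7-repeat insertion dynamics from peak intervals
    and rescaled peak areas, and provides forward Monte Carlo simulators
    for the unitary walk, periodic insertion, their combination, and an
    error-prone PCR branching process, together with a synthetic
    trace/cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
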