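Package: flowPE
Title: Genome Size and Partial Endoreplication Analysis for Plant Flow
    Cytometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating nuclear DNA content (2C-value) and the
    size of the endoreplicated genome fraction (P) from propidium-iodide
    flow cytometry of tissues with partial endoreplication, as found in
    most orchids. Provides a minimal list-mode FCS and CSV event reader,
    histogram binning, Gaussian peak detection and fitting, peak-role
    assignment against internal size standards, regression-based
    estimation of P from the 2C + k*P peak series, DNA-ploidy inference
    from fold changes in P, delineation of homoploid cryptic lineages and
    hybrid suspects from joint (2C, P) variation, taxon-level summaries
    with Tukey HSD compact letter groups, and an event-level simulator of
    partial-endoreplication fluorescence data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    methods,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
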