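Package: sporeburst
Title: Heat-Induced Resuscitation Kinetics of Thermophilic Endospores in
    Marine Sediment Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pasteurized high-temperature sediment slurry
    incubations that resuscitate dormant thermophilic endospores. Detects and
    fits biphasic exponential sulfate-reduction-rate (SRR) kinetics,
    back-extrapolates time-zero endospore censuses under configurable
    cell-specific-rate models, applies occurrence and enrichment rules to ASV
    count tables with rarefaction, weighted UniFrac and principal-coordinates
    ordination, segments sulfate and volatile-fatty-acid time series and audits
    cross-feeding stoichiometry by non-negative least squares, and normalizes
    and classifies untargeted metabolite temporal profiles with a permutation
    test for treatment clustering. A synthetic-experiment generator emulates
    the statistical structure of such incubations so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
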