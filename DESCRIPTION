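Package: denitrange
Title: Functional Operating Range of Soil Denitrifier Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates potential denitrification rates from N2O accumulation
    time series in soil microcosms, fits Gaussian temperature-response and
    power-law salt-inhibition models to derive functional operating-range
    parameters (optimum temperature, curve width, salt inhibition thresholds),
    and links them to denitrifier community diversity computed from marker-gene
    clone libraries via in-silico RFLP, richness and phylogenetic diversity
    metrics (Chao1, Shannon, Faith's PD, NRI, NTI), and phylogeny-based
    community comparison (unweighted UniFrac, AMOVA, NMDS ordination with
    vector fitting, Mantel tests). Includes a seedable synthetic-data
    generator emulating the full experimental design (gas curves, coalescent
    phylogenies, clone libraries, sequence evolution) so every stage of the
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    vegan,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
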