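Package: spongecore
Title: Core Microbiome Extraction and Seawater Overlap Analysis for
    Host-Associated Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Occurrence-based core-microbiome analysis of host-associated
    amplicon (ZOTU/ASV) count tables, developed around sponge/seawater
    comparisons. Extracts per-species core communities (taxa present in all
    replicates), identifies species-specific taxa, and quantifies the
    contribution of seawater bacteria to each sponge core against two
    seawater references (the cosmopolitan seawater core and the abundant
    seawater fraction), with rarity classification and enrichment flags.
    Includes first-principles permutation statistics (PERMANOVA, PERMDISP
    with small-sample bias correction, Dufrene-Legendre IndVal), diversity
    and clustering helpers, a seeded synthetic sponge/seawater community
    generator with planted ground truth for recovery testing, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse,
    withr
Config/testthat/edition: 3
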