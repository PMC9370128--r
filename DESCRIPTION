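Package: apricotSI
Title: S-Allele Genotyping, Incompatibility Groups, and S-Locus Diversity
    in Apricot
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining pollination requirements of apricot
    (Prunus armeniaca) cultivars under gametophytic self-incompatibility.
    Resolves S-RNase/SFB genotypes from multi-primer PCR fragment sizes via
    a disambiguation decision tree, summarizes pollen-tube microscopy
    observations into self-(in)compatibility calls, classifies cultivars as
    self-compatible or self-incompatible, allocates self-incompatible
    cultivars to cross-incompatibility groups, builds pollinizer
    compatibility matrices for orchard design, and computes S-locus
    diversity statistics per population (allele counts, rarefied allelic
    richness, private alleles, and a Monte-Carlo chi-square test of
    allele-by-country association). Ships transcriptions of published
    cultivar compilations as plain-text fixtures and a synthetic-data
    generator for populations, assays, and pistil observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
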