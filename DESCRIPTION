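Package: phyloprior
Title: Regional Phylogenetic Conservation Prioritization with EDGE2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional conservation prioritization on dated
    phylogenies. Implements the EDGE2 framework (evolutionarily distinct and
    globally endangered, version 2): extinction-probability pools per Red
    List category with pinned medians, expected-unique-phylogenetic-diversity
    (ED2) scores, and EDGE2 = ED2 x GE2 with resampling uncertainty.  Also
    provides phylogenetic diversity and fair-proportion evolutionary
    distinctiveness, DNA-barcode discriminatory-power statistics (Kimura
    two-parameter distances, diversity decomposition, barcoding-gap ANOVA),
    Red List tabulations and trait-threat rank correlations, and seeded
    generators for synthetic study-structured inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
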