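Package: profrules
Title: Association Rule Learning on Phylogenetic Presence/Absence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene function from comparative genomics by mining
    association rules over binary gene-family presence/absence profiles.
    Profiles are augmented with their logical negations so that rules may
    contain both presence and absence literals; candidate rules are found
    with a level-wise (Apriori) frequent-itemset search, scored by
    confidence, and assigned exact significance with a two-sided Fisher
    test evaluated in log space so that extreme tail masses (p below
    1e-100) remain accurate. Includes a capacity classifier for multi-gene
    pathway logic (alternative first-step enzymes plus shared downstream
    genes), a synthetic profile generator with planted pathway structure
    for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
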