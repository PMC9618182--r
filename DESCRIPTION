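Package: synaptomics
Title: Pooled-Cohort Synaptic Proteome Analysis with Ratiometric
    Thresholding, Set Specificity, Enrichment and Puncta Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of pooled tandem-mass-tag synaptic
    proteomes: unique-peptide and missing-value filtering of protein-group
    tables, case/control ratiometric values with 1/median loading
    correction, fold-change classification at the 20 percent threshold,
    stratified set-specificity and Venn logic, synapse compartment
    annotation, hypergeometric over-representation analysis with
    Benjamini-Hochberg FDR, validation statistics (orthogonal-method
    regression, summary-statistics t-tests), and array-tomography puncta
    segmentation, density and opposed-puncta colocalization. Includes
    seeded synthetic generators for cohort tables, validation panels and
    two-channel image stacks so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
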