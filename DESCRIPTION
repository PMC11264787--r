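Package: mirvasc
Title: Whole-Blood microRNA Co-Expression Networks and Vascular Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline linking whole-blood microRNA
    co-expression modules to quantitative vascular-function traits. Implements
    signed weighted co-expression network construction from biweight
    midcorrelation (soft-threshold power selection against a scale-free
    topology target, topological overlap, average-linkage clustering with a
    hybrid tree cut, module merging, eigen-miRNA summarisation and module
    membership), module-trait and hub-miRNA association models with
    Benjamini-Hochberg false-discovery control, linear mediation analysis with
    bootstrap inference on the proportion mediated, miRNA to target-gene
    confirmation against gene expression, hypergeometric term
    over-representation with semantic aggregation and Fisher combination, and
    a genome-wide miR-eQTL scan with LD clumping into loci. A synthetic-cohort
    generator with planted modules, trait couplings, target genes and
    cis-eQTLs provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
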