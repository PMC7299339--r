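Package: sproutnet
Title: miRNA-mRNA Post-Transcriptional Co-Expression Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed bipartite miRNA-mRNA post-transcriptional regulatory
    networks from two-condition expression data. Combines expression filtering
    and a simple two-condition differential-expression stage, all-pairs Pearson
    co-expression with a sample-randomization permutation null, TargetScan-style
    target-prediction filtering by weighted context++ score percentile, a
    from-scratch gene set enrichment analysis engine (two-class and continuous
    phenotypes, permutation FDR, leading-edge extraction, miRNA x gene-set
    association matrices), network assembly with degree statistics and discrete
    power-law fitting with bootstrap goodness-of-fit, hypergeometric
    over-representation, endothelial-signature cohort scoring, and delta-delta-Ct
    qPCR card analysis. A synthetic-data generator with planted regulatory
    structure provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
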