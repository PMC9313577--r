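Package: repsubsets
Title: T-Cell Subset Phenotyping and TCR Repertoire Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of human T-cell differentiation:
    marker-based classification of cells into naive, stem cell memory, central
    memory, effector memory and terminally differentiated (EMRA) subsets with
    recent-thymic-emigrant flagging and cohort-level age-trend statistics, and
    TCR-alpha repertoire analysis with Simpson's clonality and Jaccard
    clonotype overlap normalized by repeated subsampling to the smallest
    repertoire. Reads and writes clonotype tables in AIRR Rearrangement and
    immunoSEQ-export style dialects, partitions repertoires into productive
    and nonproductive fractions, and ships a synthetic repertoire and cohort
    generator that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'repertoire.R'
    'io.R'
    'diversity.R'
    'phenotype.R'
    'trends.R'
    'simulate.R'
    'pipeline.R'
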