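Package: treburden
Title: Genome-Wide Rare Tandem Repeat Expansion Discovery and Case-Control
    Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects rare tandem repeat expansions (TREs) from multisample
    depth-normalized repeat-size profiles (ExpansionHunter-Denovo style) by
    per-locus DBSCAN outlier calling with a reference-panel population
    frequency filter, applies cross-cohort locus bias filtering and
    Anscombe-transform sample quality control, annotates calls against gene
    models partitioned into functional elements (exon-junction proximity),
    and performs covariate-adjusted logistic-regression burden tests with
    label-permutation empirical p-values, carrier-proportion and
    attributable-risk estimates, and gene-set / constraint / GWAS-overlap
    enrichment statistics. Includes a synthetic cohort generator with
    planted expansions and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
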