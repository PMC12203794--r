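Package: episilence
Title: Discovery of Epigenetically Silenced Tumour Suppressor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative discovery pipeline for tumour suppressor genes
    silenced by driver-gene-associated promoter hypermethylation. Provides
    per-probe epigenome-wide association testing, a native combined-p
    differentially methylated region (DMR) caller with autocorrelation-corrected
    Stouffer-Liptak aggregation and Sidak correction, promoter/5'UTR gene
    assignment, two-group differential expression with fold-change and
    Benjamini-Hochberg control, multi-cohort Cox/log-rank survival consensus
    screening, loss-of-function versus methylation mutual-exclusivity
    stratification, and pre-ranked gene set enrichment analysis with
    permutation-based significance. A synthetic multi-cohort generator with
    planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
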