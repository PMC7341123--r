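Package: bsaqtl
Title: Bulked-Segregant QTL-seq Analysis and Mendelian Segregation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked-segregant analysis of biparental
    crosses: per-site SNP-index and delta(SNP-index) statistics with the
    standard depth and index filters, sliding-window genome scans,
    Monte-Carlo confidence bands for delta(SNP-index) under the null
    hypothesis of no QTL at given read depths, and candidate-region
    extraction.  Includes Mendelian segregation utilities (fertility
    classification, observed fertile:sterile ratios, Pearson chi-square
    goodness-of-fit against theoretical ratios) for restorer-of-fertility
    genetics, and a synthetic cross-and-sequencing simulator (F2 and
    backcross populations, extreme-phenotype bulks, Poisson/binomial read
    sampling) that emits the variant-table formats the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
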