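Package: fsvkit
Title: SNP Detection and Flanking SNPs Value Analysis for Pooled Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-nucleotide polymorphism (SNP) detection
    from low-coverage sequencing of pooled DNA samples drawn from two
    divergently selected populations. Implements read-count threshold SNP
    calling from pooled pileups, per-line reference-agreement scores, the
    Flanking SNPs Value (FSV) statistic that predicts between-population SNP
    informativity from local divergence in flanking windows, closed-form
    detection power under Poisson depth, and an evaluation layer (detection
    sensitivity by allele-frequency bin, FSV stratified by allele-frequency
    difference, Pearson correlation scans over window sizes and chromosome
    size classes). A synthetic-data generator produces line-divergent allele
    frequencies with spatial block structure, individual chip genotypes and
    pooled pileups, providing ground truth for power and recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
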