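Package: bdnascreen
Title: Barcoded DNA Screening Analysis for Pooled Lipid Nanoparticle
    Biodistribution
Version: 0.1.0
Authors@R:
    person("bdnascreen", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput organ-tropism screening of pooled,
    DNA-barcoded lipid nanoparticle (LNP) libraries. Provides a ground-truthed
    simulator of pooled b-DNA/UMI sequencing experiments (barcode whitelist
    design, planted organ tropism, PCR duplication, substitution error),
    quantification of barcodes from FASTQ via positional extraction,
    mismatch-tolerant whitelist assignment and directional UMI deduplication,
    pool-normalized enrichment statistics (two-sided Wilcoxon rank-sum tests
    with Benjamini-Hochberg FDR control) with organ-tropism candidate calling,
    and combinatorial lipid library structure-activity (hit-rate) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
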