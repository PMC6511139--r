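Package: annogwas
Title: Annotation Category-Based Significance Thresholds for GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects quantitative trait loci (QTL) by iterative conditional
    single-marker association scans, extracts linkage-disequilibrium based
    causal-candidate sets, classifies sequence variants into functional
    annotation categories (4-, 5- and 8-category schemes built from VEP
    consequence impacts and open-chromatin/UTR/regulatory-element/ncRNA
    intervals), estimates per-category causal-variant enrichment by maximum
    likelihood (EM) with bootstrap confidence intervals, and derives
    enrichment-weighted Bonferroni significance thresholds whose power is
    compared against a flat Bonferroni correction. Includes a synthetic-data
    generator (LD-block genotypes, configurable annotation landscape,
    quantitative phenotypes with category-enriched causal variants) so the
    whole pipeline is testable without access-restricted genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
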