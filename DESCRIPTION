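Package: rarebin
Title: Knowledge-Guided Binning and Burden Testing of Rare Genetic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapses low-frequency genetic variants into biologically
    meaningful bins (genes, pathways, intergenic windows, exon/intron and
    functional-prediction splits) using a local relational knowledge base,
    computes per-individual bin burden matrices from VCF genotypes with
    per-group minor-allele-frequency rarity calls, and tests case/control
    burden differences with a Wilcoxon rank-sum test under Bonferroni
    correction. Includes a forward-time Wright-Fisher rare-variant region
    simulator and a replicate harness for type-I-error, power, and spike-in
    recovery studies, plus generators for fully synthetic VCF, phenotype,
    region, and gene-set fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    vcfR,
    IRanges,
    S4Vectors,
    DBI,
    RSQLite,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
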