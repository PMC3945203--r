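Package: homeofate
Title: Homeolog Expression Resolution and Fate Classification for Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves homeolog-level gene expression in an allopolyploid
    without a close reference genome. Reads from two parental strains and
    the allopolyploid are mapped to a surrogate reference gene set;
    diagnostic SNPs are called and classified by subgenome ancestry;
    homeolog-specific, informative-region-masked references are built;
    allopolyploid reads are assigned to homeologs at zero mismatches; and
    per-gene expression fates (inheritance, blending, bias, reversal),
    expression-level dominance, extreme differential expression, gene-loss
    candidates and physical deletion clusters are classified using Fisher
    exact tests with Storey q-values. Includes a ground-truth RNA-seq
    simulator for parental and allopolyploid transcriptomes, and an
    upper-bound molecular dating estimate from lineage-specific SNP counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
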