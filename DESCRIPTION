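Package: bincomm
Title: Community Phylogenetics of DNA-Barcode BINs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phylogenetic community structure of local
    assemblages delimited by DNA-barcode Barcode Index Numbers (BINs) against a
    regional species pool. Implements ingestion and quality filtering of
    BOLD-style specimen exports, reduction of each BIN to a centroid sequence,
    distance-based neighbor-joining trees with bootstrap support and
    maximum-clade-credibility summaries, the net relatedness index (NRI) and
    nearest taxon index (NTI) as standardized effect sizes of mean pairwise and
    mean nearest-taxon distance under a tip-label permutation null, stepdown
    multiple-testing correction, and trait analyses (one-way ANOVA, chi-square
    tests on BIN representation, paired t-tests between analyses, and
    phylogenetic generalized least squares under Brownian motion). A synthetic
    data generator produces barcode-like datasets with known community assembly
    regimes (neutral, environmental filtering, repulsion) so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    picante,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
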