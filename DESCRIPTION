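Package: thermosel
Title: Branch-Site Scans for Convergent Positive Selection in Endothermic Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects convergent positive selection on the stem branches of
    independently endothermic fish lineages (tunas, lamnid sharks) from
    per-gene coding alignments and gene trees. Implements gene-tree ortholog
    pruning (spurious-tip trimming, species-repeat collapsing, deep-paralog
    cutting, rooted-ingroup duplication resolution), two stringent alignment
    filtering pipelines (aligner-concordance/consistency scoring and
    confidence masking with gap/similarity column trimming), branch-site
    codon models with likelihood-ratio tests on a marked foreground branch,
    a six-test consensus caller with per-gene Benjamini-Hochberg correction,
    synonymous-saturation screening, four-fold degenerate site supermatrix
    construction, marginal ancestral amino-acid reconstruction, and a codon
    sequence simulator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
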