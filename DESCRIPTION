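Package: permpath
Title: Permutation Testing for GWAS Pathway Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway over-representation analysis for genome-wide association
    studies with systematic permutation-based null distributions. Implements
    per-SNP quality control, the 1-df Cochran-Armitage trend test with
    optional covariate-adjusted logistic regression and genomic control,
    SNP-to-gene significance mapping, the exact hypergeometric
    enrichment/depletion test with Benjamini-Hochberg adjustment, and three
    permutation null constructions (case-control label shuffles, SNP p-value
    shuffles, gene label shuffles) together with a subsampling-based
    convergence analysis of the required number of permutations. A synthetic
    GWAS generator with linkage-disequilibrium blocks, heterogeneous gene
    sizes, overlapping pathways and planted causal pathways makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
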