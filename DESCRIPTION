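Package: aaSiteClass
Title: Site-Class Specific Amino Acid Exchangeability Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers classes of sites in amino-acid multiple sequence
    alignments by K-means clustering of per-site mean physiochemical
    property profiles (nine near-orthogonal property scales), selects the
    number of classes with the gap statistic and its 1-standard-error
    rule, and estimates a class-specific 20x20 reversible amino-acid
    exchangeability matrix for each class by maximum likelihood on a
    fixed tree topology. Includes a noise analysis that compares
    class-specific matrices against matrices fitted to random site
    partitions of equal size, likelihood cross-validation of the class
    structure, branch-length comparison and mixing utilities, a sequence
    simulator, readers and writers for FASTA, PHYLIP, Newick and
    PAML-style rate-matrix files, and a synthetic fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, Biostrings, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), phangorn, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
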