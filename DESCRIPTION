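Package: codonevol
Title: Codon Usage Bias, Ka/Ks and Branch/Site Selection Tests for Gene
    Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for coding-sequence
    gene families split into a foreground and a background species group.
    Implements Wright's effective number of codons (Nc), GC/GC3 content,
    data-driven optimal-codon detection and the frequency of optimal
    codons (Fop); pairwise Ka/Ks by Nei-Gojobori (1986) counting and a
    kappa- and frequency-corrected Yang-Nielsen-style estimator; an
    MG94xHKY codon substitution likelihood engine with Felsenstein
    pruning over branch-class-labeled trees; one-/two-/multiple-ratio
    branch models and discrete site-class (M3) models with likelihood
    ratio tests and naive empirical Bayes positive-site identification;
    gene-family-size and group-contrast summaries; and a codon-evolution
    simulator that generates alignments under per-branch-class omega and
    gene sets with planted optimal-codon gradients for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
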