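Package: hybridorigin
Title: Hybrid-Origin Inference from Multilocus Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the origin of putative homoploid hybrid taxa
    from multilocus nuclear and chloroplast sequence alignments. Provides
    per-locus polymorphism and neutrality statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, Fu and Li's D* and F*, a maximum-likelihood
    HKA test), genetic-distance principal component analysis, a Bayesian
    admixture-model Gibbs sampler with Evanno delta-K model choice, six-class
    hybrid-genotype assignment (pure parents, F1, F2, backcrosses), a
    coalescent simulator supporting population splits and pulse admixture,
    approximate Bayesian computation scenario comparison with rejection
    sampling and logistic-regression posteriors, chloroplast genetic typing
    with cytonuclear-discordance reporting, and a fully labelled synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    nnet,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
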