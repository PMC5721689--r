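Package: coalsmc
Title: Coalescent Estimation of the Scaled Mutation Rate by Tempered
    Sequential Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian estimation of the scaled per-site mutation rate
    Theta under the neutral coalescent from a sample of aligned DNA
    sequences. The posterior over the joint space of Theta, the
    substitution-model parameters (K80 or F84) and the latent genealogy
    is approximated by a likelihood-tempered sequential Monte Carlo
    sampler with pi_t-invariant Metropolis-Hastings move kernels,
    systematic resampling and an effective-sample-size trigger. A
    move-matched Metropolis-Hastings MCMC sampler is included as a
    baseline, together with a coalescent/finite-sites sequence
    simulator with known truth, Felsenstein pruning likelihoods with
    site-pattern compression, UPGMA initialization, Watterson's
    estimator, FASTA/PHYLIP/Newick input-output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
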