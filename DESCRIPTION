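Package: bbTM
Title: Substitution Rates and Scoring Matrices for Transmembrane
    beta-Barrel Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates instantaneous amino-acid substitution rate matrices
    for the transmembrane strands of beta-barrel outer-membrane proteins
    from multiple sequence alignments and fixed phylogenies, using a
    Bayesian Markov chain Monte Carlo sampler over a reversible
    continuous-time Markov model. Supports partitioning of transmembrane
    residues into barrel-lumen-facing and lipid-facing subsets, a
    valid-pairs correction for unevenly observed residue pairs, derivation
    of integer log-odds scoring matrices (the bbTM family) at chosen
    evolutionary times, Karlin-Altschul statistics, substitution-profile
    clustering, sequence simulation along phylogenies, and a local-alignment
    search harness with composition-preserving shuffled decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
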