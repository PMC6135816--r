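Package: basinfold
Title: Fragment-Assembly Conformational Sampling with Basin-Hopping Search
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained fragment-assembly engine for low-resolution
    protein structure sampling. Implements the staged Metropolis Monte Carlo
    protocol with temperature quenching used by classical fragment-assembly
    predictors, plus two basin-hopping search protocols (a bilevel scheme that
    partitions moves between loop and secondary-structure residues, and an
    iterated local search) that alternate forced structural perturbation with
    greedy local optimisation and keep an archive of the lowest-scoring local
    minima. Includes exploration analytics (per-residue accepted-move
    profiles, contact-map Hamming dissimilarities, classical multidimensional
    scaling, PAM clustering with a Markov-state entropy measure, the
    Mack-Skillings rank test), Calibur-style decoy clustering for model
    selection, and a synthetic-data generator producing toy targets, fragment
    libraries with controlled native enrichment, and noisy secondary-structure
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
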