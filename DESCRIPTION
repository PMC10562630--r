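Package: ampevo
Title: Antimicrobial Peptide Discovery and Molecular Evolution Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully seeded pipeline for studying the evolution of
    defensin and cathelicidin antimicrobial peptide (AMP) gene families.
    Provides peptide curation filters and cysteine-motif classification,
    physicochemical feature extraction with a ridge-logistic AMP probability
    classifier, Smith-Waterman local alignment with Karlin-Altschul e-values
    for best-hit subfamily assignment, transposable-element (TE) overlap
    resolution and gene-TE intersection summaries, a Bayesian phylogenetic
    hierarchical regression of gene length on TE content fitted by blocked
    Gibbs sampling, and birth-death gene-family-size likelihoods on a species
    tree with discrete-gamma rate variation, maximum-likelihood fitting,
    likelihood-ratio model comparison, per-branch change calls and a
    species-overlap duplication criterion. A synthetic-data module generates
    every input the pipeline consumes with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    phangorn,
    rtracklayer,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
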