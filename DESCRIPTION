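Package: domainmix
Title: Taxonomic Profiling of Metagenomes from Protein Domain Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the taxonomic composition of a metagenome across all
    domains of life and viruses from its protein domain frequency profile.
    The observed profile of Pfam-style domain family frequencies is
    reconstructed as a convex combination of taxonomically labeled reference
    signatures; mixture weights are estimated by expectation-maximization
    under simplex constraints and summed per taxon to give abundances. Model
    quality is quantified by the fraction of domain hits unexplained (half
    the Manhattan distance between observed and reconstructed profiles, the
    Bray-Curtis dissimilarity) and the fraction of sequences unexplained.
    Includes tools to build reference signatures from fragmented genome
    sequences, to vet metagenome-derived reference signatures by repeated
    cross-validated stepwise elimination with regularized least squares
    classifiers, and to simulate complete synthetic test fixtures with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
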