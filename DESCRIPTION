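Package: PhoreScreen
Title: Ligand-Based Pharmacophore Screening and Docking-Pose Interaction
    Fingerprint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering small-molecule binders of G
    protein-coupled receptors by ligand-based virtual screening and
    structure-based pose analysis. Provides matched-pair
    structure-activity analysis at IC50 cutoffs, common-feature
    pharmacophore construction with fit-value scoring and ROC enrichment
    against property-matched decoys, Tanimoto fingerprint similarity, and
    docking-pose post-processing via per-residue interaction fingerprints,
    Hamming-distance hierarchical clustering and structure-based pose
    filters, together with seeded synthetic-data generators for molecules
    embedding a pharmacophore and toy binding-site complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape,
    bio3d,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
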