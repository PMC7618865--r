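Package: domainkit
Title: Consensus Protein Domain Segmentation, Classification Bookkeeping
    and Domain-Pair Interaction Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for analysing predicted protein structure
    models at the domain level. Merges per-chain domain segmentations
    ("choppings") from multiple parsers into consensus domains with
    high/medium confidence tiers; books domain labels onto the CATH
    hierarchy at superfamily (H) or topology (T) depth, propagates labels
    over sequence clusters and cross-validates them against HMM scans;
    extracts interacting superfamily pairs (ISPs) from contacting,
    PAE-filtered domain pairs and scores the conservation of their relative
    orientation (CIO) by Kabsch superposition into a common frame; detects
    internal structural symmetry with a circular-shift self-superposition
    scan and a Z-score gate; ranks unlabelled domains by novelty with a
    leave-one-out k-nearest-neighbour density score on embedding vectors;
    and quantifies structural divergence within clusters of identical
    sequences via maximum pairwise RMSD and medoid selection. Seeded
    synthetic-fixture generators emit every input dialect the toolkit
    consumes, so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
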