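Package: kacpred
Title: Histone Lysine Acetylation Prediction from Peptide Clustering and
    Nucleosome Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised prediction of histone lysine acetylability.
    Flanking peptides around each lysine are compared by Smith-Waterman
    local alignment under BLOSUM62, turned into bounded raw or
    length-normalized distances, and clustered by complete linkage; the
    dendrogram cut is selected by information gain ratio and validated by
    label, normalization, histone-association and spatial-coherence
    permutation tests.  Label-pure subclasses become reference features of
    a max-min distance classifier, and a nucleosome-level spatial feature
    (numeric distances from lysine side-chain epsilon-N atoms to five
    ellipsoid regions fitted by least squares) adjusts peptide-based calls
    in a three-level hierarchical decision.  Includes generators for
    synthetic histone families and epsilon-N point clouds so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
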