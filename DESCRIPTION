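Package: hicrefine
Title: Hi-C Guided Refinement of Metagenome Bins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines metagenome bins with Hi-C proximity-ligation read pairs.
    A self-supervised random-forest classifier is trained on scaffold pairs
    drawn from the largest initial bins (intra-bin pairs as positives,
    cross-bin pairs as down-weighted negatives) using link counts, lengths,
    coverage depths and connection degrees as features. Predicted pair
    probabilities drive two refinement steps: incomplete bins are merged via
    connected components over a bin graph gated by a link-rate score, a
    depth-compatibility t-test and tetranucleotide-frequency cosine
    similarity; unbinned scaffolds are then recruited by label propagation
    over the scaffold graph. A synthetic community simulator with ground
    truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    igraph,
    ranger,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
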