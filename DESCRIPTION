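Package: topictree
Title: Streaming Headword-Based Hierarchical Document Clustering with
    Topic Filters and Tree-Structured Active Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretable exploration of large document collections via a
    streaming top-down binary cluster tree in word-embedding space.  Each
    cluster node is summarized by headwords, tokens whose summed embeddings
    are maximally cosine-similar to the embedding sum of every token that
    passed the node, so the tree stores only aggregate statistics and never
    the documents themselves.  User-defined topics are carved out of the
    tree by binary support-vector-machine filter nodes with calibrated
    probabilities, refined through labeling feedback, and a tree-structured
    active-learning strategy selects maximally informative documents from
    the widest tree level to minimize annotation effort.  Includes
    hierarchical cluster-quality evaluation (per-class best-node F1 with
    support weighting), a checkpointed active-learning simulation harness
    with random and pool-uncertainty baselines, synthetic corpus and
    embedding generators for fully self-contained benchmarking, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
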