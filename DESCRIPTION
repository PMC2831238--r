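Package: bpfs
Title: Pathway-Aware Forward Feature Selection for Two-Class Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward feature selection for two-class gene expression matrices
    that ranks candidate features by the marginal change in a linear support
    vector machine dual objective and breaks ties in biological redundancy
    using shortest-hop influence on a consolidated gene-interaction graph.
    Features that cannot be mapped to the pathway are handled through a
    probabilistic interaction model whose parameter is estimated by
    edge-subsampling reachability extrapolation. Selections over bootstrap
    resamples of the training data are combined by position-weighted rank
    aggregation. Includes a synthetic data generator with planted informative
    feature blocks and matching modular pathway graphs, plus command-line
    entry points for selection, unresolved-interaction probability estimation
    and accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
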