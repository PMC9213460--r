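Package: bdtree
Title: Breadth-Depth Tradeoffs for Finite-Capacity Planning in Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact evaluation and optimization of one-shot sample-allocation
    policies over infinitely large decision trees with binary expected rewards
    under a zero-average constraint. Implements a diffusion-maximization
    recursion that propagates the full distribution of the optimal path's
    cumulative reward across tree levels, for exhaustive, homogeneous,
    heterogeneous, two-branching-factor and temporally discounted allocation
    families under an average capacity constraint. Includes grid-search and
    projected gradient ascent optimizers, closed-form success-probability
    analytics, exact enumeration and Bellman-Monte-Carlo oracles, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
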