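Package: graphsurgery
Title: Critical Benefit-to-Cost Ratios and Single-Edge Perturbation of
    Cooperation on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of the critical benefit-to-cost ratio (b/c)*
    above which natural selection favors cooperation in the donation game
    under death-birth updating on arbitrary connected weighted networks,
    via pairwise mean coalescence times of random walks.  Implements a
    first-order perturbation theory ("graph surgery") that predicts the
    change in (b/c)* when the weight of a single edge is reduced, enhanced,
    or a new edge is added, at a per-edge cost far below full recomputation.
    Includes synthetic network generators (Erdos-Renyi with fixed edge
    count, Barabasi-Albert growth from a star seed, planted l-partition,
    and an LFR-style benchmark), edge-list input/output, epsilon-sweep and
    slope-versus-actual-change correlation experiments, greedy sequential
    edge removal against a degree-sum heuristic, and Monte-Carlo plus exact
    2^N Markov-chain validators of the underlying weak-selection theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
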