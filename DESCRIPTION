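Package: nncrn
Title: Nearest-Neighbour Correlated Random Networks and Structural Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation and analysis of l-th nearest-neighbour correlated
    random networks: Metropolis-Hastings edge rewiring that controls
    degree-degree correlations (Pearson r_l) at shortest-path distances 1
    and 2 while holding the degree sequence, and at distance 2 the full
    joint nearest-neighbour degree profile, as hard constraints. Includes
    Erdos-Renyi and truncated power-law configuration-model generators,
    Newman-Ziff union-find percolation under random edge/node failure and
    degree-targeted attack, robustness summaries (f_x%, Schneider R,
    susceptibility peaks), k-core profiles, network efficiency, the
    Molloy-Reed threshold, and a config-driven experiment grid runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
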