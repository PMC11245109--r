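Package: grnforge
Title: Simulation of Group-Structured Gene Regulatory Networks and In
    Silico Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to generate directed scale-free gene regulatory
    networks with modular group structure by preferential attachment, to
    simulate stochastic gene expression on them with a saturating
    synthesis term (Euler-Maruyama forward simulation with running-mean
    convergence checks and Jacobian-based linear stability analysis), and
    to run systematic in silico knockout screens.  Downstream analyses
    include log2 fold-change effect summaries stratified by network
    distance and group membership, hub regulator and hub target counts,
    matching of simulated effect-fraction distributions against
    Perturb-seq style significance tables via Kolmogorov-Smirnov ranking,
    gene-program discovery by truncated SVD, and cross-dataset program
    concordance via canonical correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
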