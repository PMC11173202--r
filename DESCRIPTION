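Package: spreadis
Title: Influence and Susceptibility Inference for Information Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying peer-to-peer information contagion on diffusion
    networks with heterogeneous node-level traits. Implements the nonlinear
    influence-susceptibility fixed-point algorithm that reconstructs per-node
    influence and susceptibility from multi-cascade reshare logs, an
    independent-cascade simulator under the product transmission model
    p_ij = A_ij * I_i * S_j, contagion-rate estimation, degree-preserving
    randomized null models for assortativity statistics, stylized-fact checks,
    and a windowed superspreader prediction pipeline evaluated with
    precision-recall metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
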