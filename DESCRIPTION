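Package: neuromodes
Title: Spiking Network Models of Low-Dimensional Neural Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spiking neural networks whose low-dimensional activity
    manifold is a direct consequence of the recurrent connectivity (W = K Phi),
    under three construction frameworks: echo-state reservoirs trained with
    FORCE recursive least squares, the Neural Engineering Framework (batch
    least-squares decoders over LIF tuning curves), and Efficient Coding
    networks with analytically fixed weights. Provides inside- and
    outside-manifold perturbations of the neural modes, relearning, and the
    similarity measures (element-wise weight correlations, Frobenius norms,
    principal angles between subspaces, factor-analysis loadings) used to
    quantify how much synaptic rewiring each kind of perturbation demands.
    Includes a sign-constrained, sparsity-masked solver producing Daleian
    weight matrices and orchestration functions reproducing the full
    simulation study at configurable scale.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
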