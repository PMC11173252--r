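Package: eprnet
Title: Non-Equilibrium Potential Landscapes via Entropy-Production-Rate Loss Minimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs the potential landscape U = -D log p_ss of an ergodic
    stochastic differential equation by minimizing a convex, steady-state-weighted
    force-projection loss (the entropy-production-rate loss) over a small neural
    scalar field, with a Hamilton-Jacobi-Bellman residual enhancement for small
    noise, a projected formulation for dimensionality reduction onto two prescribed
    coordinates, and a weighted-norm extension for state-dependent diffusion.
    Includes Euler-Maruyama ensemble simulators, built-in model systems (rotational
    toy, Lorenz, Gaussian-mixture gradient systems, Hill-type gene regulatory
    networks), a bilinear finite-element Fokker-Planck reference solver in two
    dimensions, entropy-production quadrature oracles, landscape error metrics, and
    seeded end-to-end experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
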