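Package: plrnnssm
Title: Piecewise-Linear Recurrent Neural Network State-Space Models
Version: 0.1.0
Authors@R:
    person("Analysis", "Group", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of nonlinear dynamical systems from noisy
    multivariate time series with piecewise-linear recurrent neural network
    (PLRNN) state-space models.  Provides the latent ReLU network process
    model and its linear (LDS) special case, Gaussian and HRF-convolved
    (BOLD-type) observation models with nuisance regressors, maximum
    a-posteriori state inference by a global Laplace approximation over the
    block-banded latent precision matrix, closed-form EM parameter updates
    built on rectified-Gaussian moment expectations, a stepwise annealing
    training protocol, state-space Kullback-Leibler measures of attractor
    reconstruction quality, Lyapunov exponent estimation, fixed-point
    enumeration and attractor classification, and ground-truth benchmark
    generators (Lorenz, van der Pol, teacher PLRNNs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
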