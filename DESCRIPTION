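Package: blanketrg
Title: Markov-Blanket Particles and Renormalization-Group Coarse-Graining of
    Linear Stochastic Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates sparse directed Jacobians (effective connectivity) from
    multivariate time series via a linearized state-space general linear model
    solved with variational Laplace and Bayesian model reduction; recursively
    partitions states into particles (internal states wrapped in Markov
    blankets) using a blanket-forming matrix and graph-Laplacian seeding;
    coarse-grains the dynamics by adiabatic reduction in the spirit of the
    renormalization group; and characterizes the resulting multiscale dynamics
    through transfer functions, stationary and cross-covariances, a
    solenoidal/dissipative (Helmholtz) decomposition at nonequilibrium steady
    state, distance power laws, and spatiotemporal scaling exponents. Includes
    a synthetic-data generator for spatially embedded linear stochastic
    systems observed through hemodynamic-like convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
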