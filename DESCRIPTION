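Package: pdpmanifold
Title: Neural Manifold Geometry and Capacity in a Spiking Model of Zebrafish pDp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates odor-evoked population activity in the posterior zone of
    the dorsal pallium (pDp) of zebrafish with a conductance-based spiking
    network carrying excitatory/inhibitory assemblies, and analyses the
    geometry of the resulting neural manifolds. Provides Euclidean and
    Mahalanobis distances between trial-pooled odor manifolds with neuron
    subsampling, a mean-field estimator of manifold capacity based on
    Gaussian-sampled quadratic programs with anchor-point effective geometric
    measures (radius, dimension, center/axes alignments), label-shuffle null
    controls, synthetic-manifold and olfactory-bulb input generators, and the
    accompanying nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
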