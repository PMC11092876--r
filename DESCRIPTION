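Package: molfm
Title: Flow Matching Generative Modeling of 3D Molecules with
    Simplex-Constrained Categorical Flows
Version: 0.1.0
Authors@R:
    person("Ian", "Mercer", email = "imercer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating flow matching generative
    models of small molecules at desk scale. Molecules are fully connected
    attributed graphs holding 3D atom positions together with categorical
    atom types, formal charges and bond orders. Categorical modalities are
    represented on the probability simplex, and flows over them can be
    constrained to the simplex via simplex-supported priors and an endpoint
    (softmax) parameterization. Includes per-modality cosine interpolant
    schedules, conditional vector fields with both vector-field and endpoint
    training objectives, several categorical prior families (uniform-simplex,
    marginal-simplex, barycenter, Gaussian) and Dirichlet conditional paths,
    optimal-transport alignment of prior and data point clouds, a rotation
    equivariant graph network built on geometric vector perceptrons with an
    optional cross-product (chirality-sensitive) variant, Euler-integration
    sampling, molecule stability/validity/energy-divergence metrics, and a
    download-free synthetic fixture generator so that the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit on the PATH (optional; used
    for molecule sanitization and MMFF energy evaluation)
Config/testthat/edition: 3
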