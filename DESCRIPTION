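Package: hyperdyn
Title: Simulation and Effective-Order Learning for Hypergraph Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating dynamical systems on hypergraphs
    (synchronization, epidemic spread, opinion formation, diffusion) and for
    learning, from state/derivative observations or trajectories, both the
    local interaction functions and the minimal ("effective") interaction
    order needed to reproduce the dynamics. Hypergraphs are represented with
    size-grouped hyperedge sets and sparse lifting operators; dynamics are
    assembled from permutation-invariant interaction kernels of configurable
    arity; the learnable model approximates per-size update functions with
    order-capped, permutation-symmetrized multilayer perceptrons trained with
    an L1 loss, and a model-corrected performance score selects the effective
    interaction order by cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
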