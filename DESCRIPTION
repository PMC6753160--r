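Package: rdcalign
Title: Alignment Tensor Analysis of Residual Dipolar Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for measuring and analysing amide residual dipolar
    couplings (RDCs) in weakly aligned proteins and large complexes.
    Computes couplings and their uncertainties from isotropic/anisotropic
    peak lists (HSQC/TROSY and IPAP), fits Saupe alignment tensors by
    singular-value decomposition, validates structures with Q factors,
    propagates experimental and structural noise by Monte Carlo, refines
    secondary-structure-element orientations against RDC restraints by
    simulated annealing, compares alignment tensors via irreducible
    five-vector angles and Sanson-Flamsteed axis projections, and
    quantifies inter-domain alignment propagation with a tensor-magnitude
    order parameter. Includes a synthetic-data generator (ideal helices,
    simulated RDC datasets and peak lists with known ground truth) for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
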