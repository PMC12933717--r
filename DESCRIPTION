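Package: aefm
Title: Adaptive Equilibrium Flow Matching for Molecular Geometry Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Structure-only refinement of noisy or low-fidelity molecular
    geometries (e.g. approximate transition-state guesses) by a learned
    time-independent equilibrium flow. A coordinate-to-coordinate network is
    trained with a noise-calibrated Gaussian corruption prior and a direct
    endpoint-prediction loss plus a physics-informed bond-consistency term,
    and applied at inference as a fixed-point iteration with optional
    Anderson acceleration. Includes Kabsch superposition and RMSD utilities,
    XYZ input/output with dataset manifests, a reference SE(3)-equivariant
    message-passing refiner, Jacobian spectral-radius convergence
    diagnostics, a synthetic benchmark generator, a Mueller-Brown
    saddle-point toy, and evaluation reports (improvement fractions,
    bond-length distribution Wasserstein-1 distances).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
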