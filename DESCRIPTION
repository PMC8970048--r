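Package: tomogan
Title: Unpaired 3D Image Translation and Classical Simulation for Cryo-ET Subtomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to synthesize realistic cryo-electron tomography (cryo-ET)
    subtomograms. Provides a cycle-consistent Wasserstein adversarial
    translation model mapping macromolecule density maps to experimental-style
    subtomograms (and back), with spectral normalization, noise-channel
    injection and Monte-Carlo-dropout uncertainty maps; a classical
    physics-based simulator (random pose, modulation-transfer-function blur,
    missing wedge, Gaussian noise at a target signal-to-noise ratio); MRC2014
    volume input/output; and a generative-model evaluation suite (inception
    score, Frechet distance, k-nearest-neighbour manifold precision, recall,
    density and coverage, 3D structural similarity, and a downstream
    classification harness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
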