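Package: foldscape
Title: Conformational Dynamics and Folding Energy Landscapes from
    Single-Molecule Magnetic Tweezers Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for equilibrium single-molecule force
    spectroscopy recordings of protein folding, built around the talin R3
    mechanosensor. Idealizes extension-time trajectories into conformational
    dwells with a threshold algorithm that excises transition paths, converts
    end-to-end fluctuations into unstructured contour length through the
    freely-jointed-chain model, reconstructs kinetic networks of rare
    conformational states, detects proline cis-trans isomer switches from the
    running unfolded fraction, recovers the folding free-energy landscape by
    Jansson deconvolution of the extension histogram, and ranks foldon-based
    structural hypotheses against the measured extensions and fluctuations.
    Includes a continuous-time Markov jump-process simulator of
    magnetic-tweezers-like trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    mclust,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
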