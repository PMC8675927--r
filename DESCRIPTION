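Package: epifold
Title: Mechano-Biochemical Simulation of Polarity-Driven Epithelial Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of apical-basal polarity and epithelial
    mechanics for fold formation in a monolayer tissue. A one-dimensional
    reaction-diffusion model of the aPKC/Par-1/Bazooka polarity network lives
    on each cell's membrane half-perimeter and exchanges material with a
    well-mixed cytosolic pool; a three-dimensional vertex model of
    hexagonal-prism cells evolves tissue shape by overdamped gradient descent
    on a surface-mechanical potential; an apical-domain-homeostasis feedback
    law modulates each cell's surface mechanics in response to shifts of the
    Bazooka peak, closing the mechano-polarity loop. Includes closed-form
    force-balance and linear-stability analysis of single cells, deformation
    metrics, perturbation scans, and command-line entry points for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
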