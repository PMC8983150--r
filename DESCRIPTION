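Package: gradchip
Title: Microfluidic Drug-Gradient Chip Simulation and Spheroid Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-inlet microfluidic
    drug-gradient chips used to screen drug combinations on 3D tumor
    spheroids. Models the chip as a hydraulic resistance network (forward
    perfusion prediction and inverse estimation of the laminar-gap depth
    from a measured perfusion rate), solves the steady-state depth-averaged
    advection-diffusion equation on the chip footprint with a monotone
    finite-volume scheme to obtain the per-column two-drug dose map, and
    analyses spheroid viability tables with Hill dose-response fits,
    Bliss-independence synergy scoring and Welch comparisons. A synthetic
    experiment generator with known ground truth makes every stage of the
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
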