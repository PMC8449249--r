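Package: hypoxfate
Title: Agent-Based Simulation of Post-Hypoxic Tumor-Cell Invasion with
    Fate-Mapped Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hypoxia fate mapping in growing tumors: a 2D
    agent-based model couples an oxygen reaction-diffusion field to cells
    that switch permanently from DsRed to GFP expression once local pO2
    drops below a hypoxia threshold, acquire a biased persistent
    random-walk migratory phenotype with tunable persistence time,
    responder fraction and gradient bias, proliferate via an
    oxygen-scaled Ki67 two-state cycle, and die below a necrosis
    threshold.  Includes a likelihood-free MCMC (approximate Bayesian
    computation) calibrator that infers migration bias and speed from
    cell-track displacement series, a synthetic track-cohort generator
    emulating spheroid cell-tracking statistics, and a Boolean
    morphometric classifier that detects invasive plumes, cell escape
    and necrotic cores in rendered or fixture images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
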