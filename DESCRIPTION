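Package: hetpop
Title: Statistical Characterization of Heterogeneous Single-Cell Receptor
    Populations and Anti-VEGF Treatment Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for statistically characterizing heterogeneous per-cell
    surface receptor populations measured by calibrated flow cytometry.
    Implements the "low bin search" procedure: maximum-likelihood fitting of
    Weibull, Gamma and lognormal distributions, selection of the histogram
    bin number that minimizes the sum of squared errors against the best
    fitting density, and a principled right-tail outlier cutoff based on bin
    occupancy. Provides representative population statistics (geometric
    mean, arithmetic mean, mode, median), tri-modal Gaussian mixture
    decomposition of multimodal tumor populations, bootstrap robustness
    protocols, synthetic population generators for testing, and a
    three-compartment VEGF/anti-VEGF kinetic-transport model to propagate
    receptor-statistic choices into predicted free-VEGF responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
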