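Package: nanoshell
Title: Core-Shell Nanoparticle Metrology from Correlated AFM and DLS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dimensional and chemical characterization of self-assembled
    core-shell nanoparticles (PEGylated gold reference series and nucleic
    acid-polyethylenimine polyplexes). Simulates atomic force microscopy
    (AFM) topographs and dynamic light scattering (DLS) intensity
    autocorrelation functions from seeded particle populations, and
    implements the inverse chain: first-order image flattening, particle
    detection and height/width measurement, shape-corrected equivalent-sphere
    diameters, log-normal size-distribution fits, cumulant and regularized
    non-negative least-squares inversion of correlograms, shell-thickness
    estimation from systematic shifts between AFM and DLS trendlines with
    curvature and polydispersity screening, root-sum-of-squares uncertainty
    budgets, polymer-brush grafting-density analysis of PEGylation
    titrations, payload-per-particle estimates, and the
    equilibrium-grafting-density growth model for polyplex cores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
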