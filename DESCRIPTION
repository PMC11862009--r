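Package: nucleoscope
Title: Morphometry, Dynamics and Polymer Modeling of Confined Nuclei and
    HP1 Condensates
Version: 0.1.0
Authors@R:
    person("Nucleoscope", "Developers", email = "nucleoscope@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mechanically confined cell nuclei imaged in
    3D fluorescence microscopy, and for confined bead-spring chromosome models.
    Provides synthetic phantom generators with ground truth (ellipsoidal
    nuclei with condensate spots, fractional-Brownian tracks, FRAP recovery
    curves, 1-Mb binned ChIP-like signal); nucleus segmentation and shape
    descriptors (elongation, flatness, sphericity); condensate detection by
    eroded-Otsu labeling with radial/peripheral distance statistics,
    radius-matched random controls and Mander's colocalization; condensate
    tracking with linear-assignment linking, mean squared displacement and
    anomalous exponent fitting; FRAP normalization and single-diffusion
    recovery fitting; a Kremer-Grest polymer model under rigid spherical or
    oblate confinement with ChIP-weighted Lennard-Jones attraction; condensate
    detection in simulations by single-linkage clustering with a
    silhouette-selected dendrogram cut; and the statistical summaries used
    throughout (Mann-Whitney tests with star notation, kernel density
    estimates, boxplot conventions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
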