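Package: epimorph
Title: Epithelial Junction Morphometry and Tight-Junction Barrier Physiology
Version: 0.1.0
Authors@R:
    person("Epimorph", "Maintainers", email = "maintainers@epimorph.dev",
           role = c("aut", "cre"))
Description: Quantifies the shape of epithelial cell-cell junctions with the
    zigzag index (the ratio of traced tight-junction path length to
    vertex-to-vertex chord length, pooled over randomly sampled windows),
    extracts junction networks from fluorescence images by thresholding,
    skeletonization and graph tracing, and profiles signal intensity along
    line scans.  A companion physiology toolkit computes transepithelial
    electrical resistance, charge selectivity (P_Na/P_Cl) from dilution
    potentials via the Goldman-Hodgkin-Katz equation, absolute ion
    permeabilities via the Kimizuka-Koketsu relation, and tracer apparent
    permeability from flux time series.  A synthetic-data module renders
    confocal-like monolayer images from Voronoi cell mosaics with
    controllable junction tortuosity and punctate myosin decoration, and
    simulates electrophysiology and tracer-flux experiments from known
    ground truth, so every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
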