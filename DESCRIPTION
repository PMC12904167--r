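Package: sarcsplit
Title: Quantification of Sarcomere Transverse Splitting, Z-Line Disarray,
    and Newly-Synthesized-Protein Hotspots in Striated Muscle Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying longitudinal muscle-fiber growth from
    two-channel fluorescence micrographs of longitudinally sectioned
    fast-twitch fibers.  Generates synthetic striated-fiber images with
    exact planted ground truth (periodic Z-line striations, Y-shaped
    transverse-split bifurcations, newly-synthesized-protein hotspots
    rendered under three sarcomerogenesis models, PSF blur and
    Poisson-Gaussian noise); segments and traces orientation-coherent
    continuous Z-lines to measure disarray; counts net transverse splits
    per A-band across the fiber width; detects NSP hotspots by local
    background fold-thresholding with sarcomere-scale size gates and
    classifies their morphology against Z-line-splitting and
    H-zone-splitting models; and provides single-fiber morphometry
    (serial sarcomere number) with the accompanying statistical
    procedures (outlier exclusion, relative-to-control normalization,
    t tests, one- and two-way ANOVA with Tukey and Fisher LSD post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    tiff,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
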