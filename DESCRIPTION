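Package: bactrack
Title: Segmentation, Tracking and Anomalous-Diffusion Analysis of
    Bacterial Surface Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the surface motility of rod-shaped bacteria at
    expanding colony edges from time-lapse micrographs. Frames are
    segmented by contrast enhancement, Otsu thresholding and watershed
    splitting; cells are measured by their equivalent ellipse and linked
    into trajectories by nearest-neighbour association. Trajectories are
    summarized by time-averaged and ensemble mean squared displacement,
    two-regime power-law exponents with a fixed or free crossover time,
    the fraction of cells displacing beyond a multiple of the body
    length, the zero-displacement fraction, and per-cell exponent
    distributions. A synthetic-data module simulates fractional Brownian
    motion and persistent-random-walk trajectories with an immobile
    subpopulation and renders them into noisy image stacks, so the whole
    pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
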