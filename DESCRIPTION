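Package: territoryshape
Title: Chromosome-Territory Conformation and Genomic-Locus Dynamics from
    Live-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mesoscale chromosome-territory conformation and
    genomic-locus dynamics from live-cell fluorescence imaging. Computes the
    2D gyration tensor and principal-axis aspect ratio K of a territory
    backbone curve, classifies conformations as extended or collapsed by
    two-component Gaussian mixture fitting of the K distribution (EM or
    histogram least squares), and compares conditions with Fisher's exact
    test. For single-particle tracking it drift-corrects locus trajectories
    against a nuclear-centroid reference, estimates the overlapping-window
    mean squared displacement, fits the anomalous-diffusion power law
    MSD = 4*D_app*t^alpha, and derives the trajectory gyration radius R_g
    and short-lag effective diffusion constant D_eff, with Welch group
    comparisons. Includes spike-in ChIP-seq depth-normalization scale
    factors, an imaging stage (maximum-intensity projection, Otsu
    segmentation, skeleton-based backbone extraction), and synthetic-data
    generators (worm-like-chain territory curves, Gaussian K mixtures,
    exact fractional-Brownian-motion trajectories, Gaussian-spot z-stacks
    with Poisson noise) so every stage is testable against known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
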