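Package: planarpolarity
Title: Quantification of Planar Cell Polarity from Junctional Protein Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-scale quantification of planar polarity from 2D fluorescence
    images of epithelia with skeletonized segmentations. Implements three
    polarity readouts operating on per-cell angular intensity profiles: a
    shape-insensitive weighted-PCA method (cell compression to a regular shape,
    intensity-as-radius embedding, eigenvalues of the weighted covariance), a
    second-harmonic Fourier tensor method, and a rotating-quadrant Ratio
    method. Also provides cell morphology and topology metrics (least-squares
    ellipse fitting, eccentricity, shape regularity, junction counts),
    tissue-scale polarity statistics on axial data (vector averages,
    coarse-graining, neighbor polarity, circular angle variance, weighted
    circular histograms), a synthetic epithelial cell generator with ground
    truth for validation, and batch image processing with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
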