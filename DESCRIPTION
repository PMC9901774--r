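Package: cardiomap
Title: Automated Action Potential Metrics from Optically Mapped Cardiac Microtissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of voltage-sensitive-dye optical mapping
    recordings of hiPSC-derived 3D cardiac microtissues. Segments individual
    microtissues from multi-tissue movies via per-pixel Fourier amplitude maps
    and histogram thresholding (Otsu and minimum cross entropy), removes
    baseline drift with an iterative asymmetric least squares polynomial fit,
    normalizes fluorescence (dF/F0), denoises with an edge-preserving 1-D
    bilateral filter, and extracts eight action-potential shape metrics
    (stimulation delay, upstroke rise time, APD30/50/80, APDmxr, APDtri,
    excitability) with a moving-average-subtraction detector. Includes a
    population-of-models simulator of the O'Hara et al. human ventricular
    action potential with Gaussian conductance heterogeneity and selective
    ion-channel-block scenarios, plus PCA feature extraction and multinomial
    logistic regression to identify the blocked channel from metric changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
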