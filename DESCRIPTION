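Package: restingstop
Title: Resting-State Local Connectivity and Stop-Signal Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking resting-state local
    functional connectivity to stop-signal inhibition performance. Implements a
    stop-signal task engine (dual interleaved staircases, horse-race subject
    simulation, SSRT estimation), a synthetic fMRI cohort generator with known
    brain-behavior couplings, spatial smoothing and temporal band-pass
    preprocessing, regional homogeneity (Kendall's coefficient of concordance)
    and fractional amplitude of low-frequency fluctuation maps, voxelwise full
    and age-partialled correlation with behavior, Monte-Carlo cluster-extent
    correction, and a maximum-r conjunction of the two correlation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
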