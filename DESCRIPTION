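Package: rumbleR
Title: Seismo-Acoustic Detection and Monitoring of Elephant Rumbles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring low-frequency elephant vocalizations
    (rumbles) with co-located seismic and infrasound sensors. Provides a
    synthetic seismo-acoustic scene generator with known ground truth
    (tonal rumbles with harmonics, broadband footfall transients, diurnal
    anthropogenic noise with monochromatic machine lines), spectrogram
    preprocessing and fixed-size snippet-image rendering, a convolutional
    neural network for rumble/noise classification with within-domain and
    cross-domain evaluation protocols, continuous-record scanning,
    event-catalog temporal analytics (inter-call interval histograms,
    locomotion coincidence, activity series, cross-domain matching), and
    three-component particle-motion polarization analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
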