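Package: eegsr
Title: Spatial Super-Resolution of EEG with a Linear Convolutional
    Encoder-Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates multi-channel EEG from current dipoles in a
    three-concentric-shell spherical head model, produces channel-subsampled
    and interpolated low-resolution recordings, recovers 64-channel
    super-resolution data with a linear convolutional encoder-decoder
    network trained by Adam on a mean-squared-error loss, and evaluates the
    recovery at the sensor level (mean squared error, Pearson correlation,
    evoked-potential component amplitude and latency) and at the source
    level with an array-gain minimum-variance beamformer (amplitude and
    localization error, focality, detected-source counts). Includes a
    synthetic auditory-evoked-potential generator so the full pipeline can
    be exercised without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
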