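Package: fallgan
Title: Unsupervised Fall Detection in Depth Video via Future-Frame
    Prediction GANs
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a sequence-to-sequence generative adversarial network
    on depth (or thermal) video of normal daily activities only, and flags
    falls as anomalies at inference time. The generator predicts four
    future frames from eight observed frames; anomaly evidence is the
    angle between bottleneck encodings of the reconstructed and authentic
    frame sequences, which is robust to depth-sensor hole pixels and
    frame-to-frame jitter. Includes depth-frame hole filling, a patch
    based least-squares discriminator, an optical-flow consistency loss
    with a classical differentiable flow estimator, frame-level ROC
    evaluation, and a deterministic synthetic depth-video simulator so the
    whole pipeline trains and validates on one CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
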