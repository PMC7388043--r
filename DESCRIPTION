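Package: nightcough
Title: Nocturnal Cough Recognition, Segmentation, and Sex Assignment from Smartphone Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring nocturnal cough in smartphone audio recordings.
    Implements an imbalance-aware ensemble of small convolutional neural networks
    that recognizes 650 ms cough windows in log-Mel spectrograms (participant-disjunct
    folds, balanced minibatch training, tuned decision threshold), segmentation and
    counting of coughs and cough epochs from continuous recordings via sliding-window
    scoring, a decibel silence filter and run-length postprocessing rules, and sex
    assignment of cough and cough-epoch signals with per-sex diagonal-covariance
    Gaussian mixture models over MFCC/delta/zero-crossing-rate features. Includes a
    synthetic night-audio generator with ground-truth annotations so every stage is
    testable without field recordings, WAV and Audacity label-track input/output, and
    the standard evaluation metrics (sensitivity, specificity, MCC, ROC/PR curves,
    Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
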