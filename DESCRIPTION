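Package: stae
Title: Sparse Temporal Autoencoder for Unsupervised ECG Anomaly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised electrocardiogram (ECG) anomaly detection with a
    dual-branch temporal convolutional network (TCN) autoencoder. Records are
    encoded jointly in the time domain and in a short-time Fourier transform
    (STFT) spectrogram domain, fused with a strided-block sparse attention
    mechanism with global mean-logit fusion, and reconstructed together with a
    per-timepoint log-variance. Training uses masked reconstruction with an
    uncertainty-weighted loss on normal recordings only; anomaly scores are
    uncertainty-weighted reconstruction errors. Includes a synthetic ECG
    generator with controllable rhythm, morphology and high-frequency
    anomalies, a preprocessing pipeline (band filtering, per-lead min-max
    normalization, signal-quality exclusion), ROC/Youden-index evaluation, and
    a command-line interface. All network layers and gradients are implemented
    in plain R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
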