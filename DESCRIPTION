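Package: eegr2g
Title: Region-to-Global Hierarchical BiLSTM Emotion Recognition from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hierarchical spatiotemporal feature learning for multichannel
    EEG emotion recognition. Differential-entropy band features are encoded
    region-by-region and then globally with shared-weight bidirectional LSTM
    networks, a learned region-attention layer weights the contribution of
    each brain area, and an optional domain discriminator trained through a
    gradient-reversal layer aligns features across subjects. Includes
    electrode-to-region topologies for 32- and 62-channel 10-20 montages, a
    synthetic EEG generator with planted regional band effects and subject
    domain shifts, supervised and adversarial AdaGrad training loops,
    trial-wise and leave-one-subject-out evaluation, per-band and ablation
    experiments, and region-contribution maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
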