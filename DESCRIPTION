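Package: surgseq
Title: Sequence-to-Sequence Surgical Workflow Segmentation with Event-Based Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-level surgical workflow segmentation for long, highly
    variable procedures such as laparoscopic sacrocolpopexy. Provides
    sequence-to-sequence temporal models (LSTM and transformer encoder-
    decoders) in time-synchronous and time-shifted configurations, three
    target-sequence training strategies (groundtruth, noise-injected, and
    fine-level predictions), sliding-window whole-video inference with
    recursive target propagation, a mode-average baseline filter, and both
    frame-based (macro precision/recall, F1, micro accuracy) and event-based
    (Ward error taxonomy with event ratio) evaluation. A semi-Markov workflow
    simulator and a configurable-accuracy feature/label emitter make the full
    pipeline reproducible on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
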