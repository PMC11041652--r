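Package: pavcond
Title: Analysis of Cue-Punishment Pavlovian Conditioning Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multimodal recordings from aversive
    (cue-punishment) Pavlovian conditioning experiments: spike-train
    featurization and foot-shock response classification with a bounded
    modulation index and low-dimensional embedding; trial-aligned calcium
    dF/F0 and AUC response classification with a longitudinal plasticity
    contingency test; per-neuron eyeblink decoding with an RBF support
    vector classifier and shuffle null; fiber-photometry photon-count
    transient analysis with a signal-validity criterion and binned peak
    statistics; and eyeblink conditioned-response scoring with a cue
    discrimination score. Includes a synthetic-data generator that plants
    the statistical structure each stage assumes (task schedules,
    rate-coupled spike modulation, calcium plasticity, coupled behavior,
    and stable or potentiating neurotransmitter sensors) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
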