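Package: epiphys
Title: Quantification of Astrocyte Calcium Transients and Hippocampal
    Electrophysiology in Kindling Epilepsy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo and in vivo recordings used to
    characterise hippocampal hyperexcitability in chemically kindled epilepsy
    models. Implements astrocyte calcium transient detection from soma
    fluorescence traces (delta-F/F0 baseline estimation, threshold event
    detection, multi-peak splitting, percentile-based fast/slow
    classification), spontaneous and evoked postsynaptic current metrics
    (event frequency and amplitude, paired-pulse ratio,
    excitatory/inhibitory balance from compound currents), field EPSP
    input-output analysis with population-spike thresholds, and local field
    potential analysis (multitaper spectra, interictal spike and
    after-discharge detection). A companion set of synthetic-signal
    generators with ground truth makes every stage verifiable without raw
    recordings, and a statistics layer reproduces normality-gated two-group
    and multi-group comparisons with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    nortest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
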