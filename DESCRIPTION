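Package: plcvrfe
Title: Phase-Measurement-Based EEG Channel Selection for P300 Spellers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Channel selection for P300 matrix spellers based on circular
    phase statistics of ongoing EEG oscillations. Implements instantaneous
    phase extraction via the analytic signal, the phase locking value (PLV),
    inter-trial coherence (ITC), the two-channel phase concentration value
    (PCV), their combination PLCV, and the target effect (TE) contrasting
    target and non-target stimulus responses. Channels are ranked by
    recursive feature elimination driven by hierarchical clustering of the
    pairwise TE similarity matrix (PLCV-RFE). Includes the full evaluation
    loop (Fisher linear discriminant character decoding, error-versus-channel
    curves, optimal channel subset selection), a seeded simulator of
    row/column speller sessions under the oscillatory phase-resetting model,
    and readers/writers for EDF recordings, event tables and rank lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
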