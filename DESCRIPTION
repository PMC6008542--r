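Package: scclfp
Title: Intraoperative Subcallosal Cingulate LFP Analysis of Acute DBS Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative local field potentials
    (LFPs) recorded from deep brain stimulation (DBS) leads in the
    subcallosal cingulate. Reads EDF+ recordings with sidecar artifact,
    cycle and clinical tables; performs zero-phase bandpass filtering,
    decimation to 128 Hz, discard-style artifact pruning and bipolar
    differential derivation; estimates per-band relative power change
    between pre- and post-stimulation epochs via complex-Morlet continuous
    wavelet spectrograms and a bootstrap confidence interval of a
    median-based relative-change statistic; and applies exact nonparametric
    group statistics (Wilcoxon signed-rank and rank-sum by full enumeration,
    Hedges' g, Bonferroni control) together with HDRS17-based clinical
    response definitions. A seeded synthetic-cohort generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
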