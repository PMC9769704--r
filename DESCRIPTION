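Package: ecogsd
Title: Band-Power and Spreading-Depolarization Analysis of ECoG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multichannel electrocorticography (ECoG)
    recordings around an ischemic insult: zero-phase preprocessing (notch,
    AC-coupling views, near-DC reconstruction), Welch-style band-power
    decomposition of 5-minute epochs into the delta/theta/alpha/beta/gamma
    bands, detection and segmentation of spreading depolarizations (SDs) as
    negative near-DC shifts with propagation linking and per-electrode
    incidence histograms, and exact small-sample nonparametric statistics
    (Wilcoxon signed-rank by enumeration, tie-corrected Friedman) for paired
    comparisons across animals and across SD phases. A ground-truthed
    synthetic-recording generator emulates ischemic-core, penumbral and
    remote electrode phenomenology so that every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
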