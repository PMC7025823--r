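Package: cocultol
Title: Co-Culture Growth Kinetics, pH Inference, and Antibiotic Tolerance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synthetic Lactobacillus-Acetobacter
    co-culture experiments: plate-reader growth-curve kinetics (mean-filter
    smoothing, instantaneous rates, modified Gompertz lag/growth-rate fits),
    an additive-model interaction score, ratiometric BCECF pH calibration and
    inversion, MIC calling from two-fold dose-response plates, time-kill curve
    fitting with MDK99-based resistance-versus-tolerance classification,
    single-cell aspect-ratio species classification with elongation-rate
    summaries, and Bonferroni-corrected pairwise Student's t-tests. Includes a
    seeded mechanistic generator (consumer-resource ODE with lactate
    cross-feeding, cardinal-pH growth modulation, Baranyi lag state, and
    pH-history-coupled killing) that produces ground-truthed plate-reader,
    CFU, dose-response, and cell-track tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
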