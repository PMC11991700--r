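Package: thermodrift
Title: Drift-Diffusion Modelling of Thermal Chamber Preference and
    Warm-Stimulus Calcium Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-chamber thermal preference behaviour and
    warm-stimulus calcium imaging of sensory neurons. Converts keypoint
    tracking output into cleaned 1 Hz position traces, chamber visits and
    descriptive preference statistics; models chamber-leaving decisions as
    first passages of a drift-diffusion process with across-visit drift
    variability, including an analytic first-passage-time density, censoring
    via survival mass, hierarchical Bayesian estimation of drift and noise
    over genotype, temperature combination and chamber with per-animal random
    effects, and model comparison by Pareto-smoothed importance-sampling
    leave-one-out cross-validation; and processes fluorescence recordings
    (neuropil correction, dF/F0, stimulus phase segmentation, responder
    classification, response onset timing, per-field-of-view summaries).
    Ships synthetic-data generators with known ground truth so every stage of
    the pipeline can be validated end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    zoo,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
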