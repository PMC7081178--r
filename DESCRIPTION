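Package: schemabg
Title: Schema Selection Through Simulated Basal Ganglia Loops on the Wisconsin Card Sorting Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rate-coded simulation of hierarchical schema selection in which
    cortical rule (cognitive) and card-placement (sensorimotor) schemas compete
    through segregated cortico-striato-thalamo-cortical loops. The model performs
    the unambiguous 24-card ("Madrid") variant of the Wisconsin Card Sorting
    Test, learns by reward-driven adaptation of striatal activation thresholds
    and conflict-driven adaptation of cortical gain, and reproduces
    healthy-control and Parkinson's-disease behavioural profiles (perseverative,
    set-loss and integration errors; response times in processing cycles).
    Model-internal proxies of two event-related potential components (the
    error-related negativity and the posterior switch positivity) are computed
    from cycle-level schema activations, together with drivers for group
    simulations, parameter-space grids, rank-correlation analyses and
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
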