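Package: pulserate
Title: Information Transmission Rate of Pulsatile Cell Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the information transmission rate (bitrate) of a
    signaling pathway stimulated with random light-pulse trains, as quantified
    from single-cell kinase-translocation-reporter trajectories. Implements
    stimulation protocol design (binary de Bruijn slots, geometric-interval
    encoding with an optional minimal gap) with exact input entropy rates,
    two-step trajectory normalization and low-variability track rejection,
    sliding-slice k-nearest-neighbour reconstruction of the pulse train with
    hard voting, conditional-entropy bounds from confusion and contingency
    tables with a permutation-averaged decomposition of information loss, and
    a reconstruction-free neighborhood entropy estimator with Miller-Madow
    bias correction. A synthetic trajectory generator emulating measured
    ERK response phenomenology makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
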