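Package: tutorsim
Title: Two-Stage Tutor-Student Motor Learning in Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-stage motor learning in conductor-student-tutor
    circuits of the kind found in the songbird vocal system (HVC, RA, LMAN).
    Provides a linear rate-based network trained by a two-timescale
    heterosynaptic plasticity rule, the analytically matched error-integrating
    tutor signal together with its saturating and reinforcement-learned
    variants, a leaky integrate-and-fire spiking realization with AMPA/NMDA
    synapses and activity-dependent inhibition calibrated to songbird-like
    firing statistics, spike-train statistics with hysteresis burst detection,
    and reproducible experiment drivers for matched learning, tutor-student
    mismatch sweeps, credit mis-assignment, and reward-driven tutor learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
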