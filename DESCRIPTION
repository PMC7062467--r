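Package: fictloc
Title: Fictive Locomotion Burst Metrics, Calcium Phase Coupling and
    Motoneuron Excitability Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spinal locomotor network output and its
    cholinergic modulation from in vitro recordings. Implements ventral-root
    burst detection on rectified/leaky-integrated traces with per-burst
    frequency, duration and amplitude metrics, time-course normalization and
    epoch comparisons; conversion of ROI fluorescence to dF/F0 with bleach
    correction and Ca2+ transient detection; mapping of transient times onto
    locomotor-cycle phase with circular summary statistics and the Rayleigh
    uniformity test; extraction of intracellular spike and excitability
    features (dV/dt spike onset, half-width, mAHP, inter-spike AHP, rheobase,
    depolarizing block, maximum firing, input resistance, ramp threshold);
    normality-gated statistical test selection; and seeded synthetic-data
    generators for all three recording modalities so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
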