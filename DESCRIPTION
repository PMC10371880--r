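Package: cppopt
Title: Multi-Window Weighted Optimal Cerebral Perfusion Pressure Trends
Version: 1.0.0
Authors@R:
    person("Alex", "Morgan", email = "alex.morgan@example.org",
           role = c("aut", "cre"))
Description: Continuous, autoregulation-oriented targeting of cerebral
    perfusion pressure (CPP) for neurocritical care time series. Computes
    the pressure-reactivity index (PRx) from 10-second averaged arterial
    blood pressure and intracranial pressure, fits Fisher-transformed
    PRx-CPP parabolas over 36 look-back windows (2-8 h), applies a stack
    of curve-acceptance criteria, and combines accepted nadirs into a
    minute-by-minute CPPopt trend smoothed with an exponentially weighted
    average. Includes the earlier multi-window weighting variant for
    comparison, a Fourier phase-randomization surrogate generator for
    false-positive testing, a virtual-patient simulator with a known
    ground-truth optimum, and trend quality metrics (stability index,
    yield, deviation from optimum, jump counts, plausibility).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
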