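Package: synclamp
Title: Effective Synaptic Conductance Estimation Under Somatic Voltage Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the space clamp effect distorts synaptic
    conductance measurements made with somatic voltage clamp, and to recover
    effective excitatory and inhibitory conductances where the traditional
    slope-and-intercept decomposition fails. Provides a passive/active
    branched-cable compartmental simulator with an ideal somatic clamp and
    dynamic-clamp style double-exponential synapses, transfer-resistance
    (two-port) measurement and closed-form static theory for the clamp-mode
    current-voltage line, per-time-point I-V regression estimators including
    the intercept method, and orchestration of reduced-scale clamp-protocol
    experiments on synthetic morphologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
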