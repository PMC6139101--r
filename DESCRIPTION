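Package: statetrait
Title: Simulation of Coupled State-Trait Dynamics in Psychotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulator of a synergetic model of psychotherapy
    change. Five psychological state variables (emotions, problem intensity,
    motivation to change, insight, therapeutic success) evolve through coupled
    nonlinear difference equations whose interaction functions are modulated
    by four trait parameters (alliance disposition, cognitive competencies,
    behavioral resources, trait motivation). Traits in turn evolve on a slower
    time scale, driven by exponentially weighted deviations of recent states,
    with saturation and threshold gating, and optionally by an empirical
    therapeutic-alliance series. Includes an intervention and dynamic-noise
    scenario engine, preset scenarios, trait-override (ramp) experiments,
    reporting transforms (z-scores, gliding-window smoothing, transition
    summaries), scenario/trajectory serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
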