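Package: thetastim
Title: Closed-Loop Theta-Phase-Specific Stimulation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of closed-loop, theta-phase-specific
    optogenetic stimulation experiments. Generates synthetic hippocampal
    local field potentials with known ground truth (quasi-periodic 4-10 Hz
    theta with cycle-to-cycle frequency drift, 1/f background noise, and
    theta-phase-modulated gamma bursts), emulates a causal real-time
    phase-prediction stimulation algorithm alongside fixed-frequency
    controls, evaluates phase-targeting performance with quarter-cycle
    sensitivity/specificity, quantifies theta-gamma phase-amplitude
    coupling via the Kullback-Leibler modulation index and comodulograms,
    computes multitaper spectrograms split by behavioral state, scores
    freezing behavior and light-induced freezing from motion traces, and
    runs the associated group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
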