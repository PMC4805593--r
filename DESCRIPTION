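Package: bgcompete
Title: Competing Basal-Ganglia Pathway Simulator for Decision-Making and
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates action selection as a dynamic competition between the
    direct (motor-facilitating) and indirect (motor-suppressing) basal-ganglia
    pathways of a single action channel.  Each channel is a two-population
    mutual-inhibition attractor network with recurrent self-excitation; the
    normalized difference of the two firing rates is accumulated to an
    execution threshold to produce go/no-go and two-alternative forced-choice
    behaviour.  The network layer is extended with cued-expectation modulation
    of baseline excitability, phasic-dopamine-like reinforcement updates of
    pathway sensitivities alongside delta-rule action values, and tonic
    background drive controlling the exploration-exploitation tradeoff.  An
    EZ-style moment inversion recovers effective drift-diffusion parameters
    (drift rate, boundary, non-decision time) from simulated trial sets, and a
    seeded configuration/serialization layer plus a command-line interface
    make every simulation reproducible end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
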