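Package: implantfatigue
Title: Probabilistic Fatigue-Life Analysis of Osseointegrated Dental Implants
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pipeline for probabilistic fatigue-life assessment of dental
    implants embedded in two-layer (cortical/trabecular) bone. A linear
    elastic plane-strain finite element surrogate resolves load transfer
    from an oblique masticatory force to the implant neck; first-order
    second-moment (FOSM) analysis propagates random load magnitude and
    titanium elastic modulus to stress/strain statistics at the critical
    point; Neuber's rule with Ramberg-Osgood cyclic hardening and the
    Coffin-Basquin-Manson strain-life relation convert these into mean
    and variance of cycles to failure; and a Bogdanoff-Kozin Markov-chain
    cumulative damage model (unit-jump chain with an absorbing failure
    level) turns the life moments into failure-probability-versus-cycles
    curves via the shifted negative-binomial absorption-time distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
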