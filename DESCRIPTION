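Package: drosdecide
Title: Spiking-Network Model of Drosophila Linear and Nonlinear Visual Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clock-driven leaky integrate-and-fire simulator of the fly
    visual decision-making system, with a fast linear central-complex pathway
    and a value-based mushroom-body pathway gated by a dopamine-APL-Kenyon-cell
    loop. Implements aversive conditioning with spike-timing-dependent
    plasticity and phasic dopamine weight depression, a conflict monitor that
    routes stimuli between the two pathways, preference-index choice assays,
    multi-cue gain-gating, and desk-scale agent tasks (window crossing,
    obstacle avoidance, online reversal learning).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
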