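Package: amygate
Title: Amygdala-Gated Thalamocortical Circuit Simulation of Emotional Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rate-coded and spiking simulators of a neural circuit in which
    the amygdala gates attention through the inhibitory thalamic reticular
    nucleus (TRN). Shunting on-center off-surround dynamics implement
    competition between cortex-TRN-thalamus loops; reinforcement-gated
    Hebbian plasticity lets the amygdala label stimuli as appetitive or
    aversive; local interneurons driven by expectation-confirmation and
    expectation-violation signals reset attention and plan selection.
    Includes builders for Pavlovian conditioning and emotion-induced
    blindness (attentional rubbernecking) protocols, interneuron lesion
    experiments, trace analysis and plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    patchwork,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
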