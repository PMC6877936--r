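Package: dgsnn
Title: Spiking Network Model of Pattern Separation and Integration in the
    Dentate Gyrus with Adult Neurogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a spiking neural network of the dentate gyrus driven by
    lateral entorhinal cortex input, with adaptive exponential
    integrate-and-fire neurons (granule, mossy, basket and HIPP cells),
    conductance-based AMPA/GABA synapses, spike-timing-dependent plasticity on
    the perforant path, and a five-stage adult-neurogenesis maturation process
    for newborn granule cells. Provides generators for binary concept stimuli
    with controlled pairwise similarity, population-rate similarity metrics and
    the pattern separation index, and experiment drivers for pairwise
    separation/integration sweeps and multi-context concept-coding protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
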