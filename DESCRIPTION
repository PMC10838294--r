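Package: hydrateRTM
Title: Reactive Transport Modeling of Microbial Organic Carbon Degradation
    in Methane Hydrate-Bearing Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A one-dimensional reactive transport simulator for
    microbially-mediated degradation of particulate organic carbon (POC)
    in layered marine sediments and the resulting formation of methane
    hydrate in coarse-grained beds. The reaction network couples
    extracellular-enzyme-driven POC hydrolysis, fermentation of
    high-molecular-weight dissolved organic carbon, methanogenesis of
    low-molecular-weight dissolved organic carbon, and first-order enzyme
    decay, with reaction rates scaled by per-lithology microbial cell
    densities. Solutes diffuse within a closed, uniformly buried sediment
    interval (Lagrangian frame, zero-flux boundaries); dissolved methane
    partitions into hydrate by local thermodynamic equilibrium against a
    depth-dependent solubility curve. The time loop is a second-order
    three-fractional-step (Strang) scheme: implicit Crank-Nicolson
    diffusion half steps around an explicit midpoint reaction step.
    Includes site presets for a thick-sand passive-margin setting and a
    thin-sand active-margin setting, rate-constant grid sweeps with
    constraint-region extraction, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
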