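Package: spillweb
Title: Oil-Spill Impact Simulation on a Spatial Age-Structured Food Web
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced, spatially explicit, age-structured marine ecosystem
    simulator forced by a polycyclic aromatic hydrocarbon (PAH) exposure and
    toxicity overlay. Gridded daily PAH concentration fields are aggregated to
    model polygons and converted to per-group mortality and growth-rate
    modifiers through first-order uptake-depuration body-burden kinetics and
    hockey-stick dose-response models, weighted by each group's reliance on
    benthic prey. Scenario machinery composes oil toxicity, fishery closures
    and larval-mortality forcings, runs a sensitivity grid over the
    sediment concentration factor K and the mortality threshold beta, and
    computes recovery times, biomass minima, age-structure shifts, condition
    factor, per-capita consumption and ecosystem indicators from paired
    impacted-versus-baseline runs. Synthetic generators supply every input, so
    the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
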