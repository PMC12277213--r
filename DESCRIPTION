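Package: berryflux
Title: Process-Based Simulation of Blueberry Fruit Growth Driven by
    Carbon and Water Fluxes Under Abscisic Acid Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of an individual blueberry fruit as a
    biophysical single-cell compartment exchanging carbon and water with
    the plant. Endogenous abscisic acid (ABA), accumulated as an
    empirical beta-growth function of cumulative growing degree hours,
    acts as a ripening signal that modulates active sugar uptake,
    ripening respiration, membrane hydraulic conductivity and fruit-skin
    permeability. The package provides hourly weather ingestion and
    synthesis, the coupled dry-mass/water-mass integrator, climate
    what-if scenarios (temperature offsets, anthesis shifts),
    goodness-of-fit statistics (MAE, RMSE, NRMSE, refined index of
    agreement, Nash-Sutcliffe efficiency), one-at-a-time local
    sensitivity analysis, and a seeded two-stage calibration routine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
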