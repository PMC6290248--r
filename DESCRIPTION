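Package: wintercarb
Title: Process-Based Modelling of Winter Carbohydrate Dynamics and Frost
    Hardiness in Walnut Branches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the temperature-driven interconversion of starch and
    soluble sugars (glucose + fructose + sucrose, GFS) in walnut branches over
    the leafless period, under a sequential chilling/forcing dormancy model.
    Three model variants of increasing mechanistic detail (zero-order,
    substrate-limited, Michaelis-Menten) share a stage- and
    temperature-dependent catalytic rate law and a Q10 respiration term.
    Includes multistart Nelder-Mead calibration from Latin hypercube starts,
    Nash-Sutcliffe efficiency and RMSE/RMSEP evaluation, a sliding-window
    temperature-physiology correlation scan, an osmo-hydric frost-hardiness
    predictor, and a synthetic-data generator emulating orchard monitoring and
    controlled-temperature branch-storage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
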