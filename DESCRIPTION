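Package: myconet
Title: Carbon-Phosphorus Exchange Analysis for Arbuscular Mycorrhizal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphology-based quantification of reciprocal carbon-phosphorus
    exchange in arbuscular mycorrhizal (AM) fungal networks. Provides a
    synthetic-data generator for network timelapses, phosphorus-depletion
    assays and hyphal-transect intensity profiles; network morphometry
    (lengths, surfaces, volumes, convex-hull area, wave speed, radius
    distributions); a feature-based regressor mapping 120-sample intensity
    transects to hyphal radius; carbon-expenditure and phosphorus-supply flux
    estimation with transporter-limited depletion calibration; a radial
    branching-anastomosis traveling-wave growth model with integral
    exchange-rate feedback; and isoexchange Pareto-front and strategy-sweep
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    xgboost
Config/testthat/edition: 3
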