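Package: rotaclim
Title: Climate-Change Impact Assessment for Rice-Wheat Rotation Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for assessing climate-change impacts on
    rice-wheat rotation cropping: stochastic station weather generation
    (Markov-chain/gamma WGEN with correlated temperature and radiation
    residuals), a configurable pseudo-GCM monthly ensemble, two-step
    statistical downscaling (inverse-distance spatial interpolation with
    empirical quantile-mapping bias correction, then monthly-conditioned
    temporal disaggregation), per-scenario yearly atmospheric CO2
    trajectories, a simplified process-based rotation crop simulator
    (thermal-time phenology with vernalization and photoperiod, RUE biomass
    with CO2 and heat-stress modifiers, bucket soil water with
    transpiration-efficiency CO2 response), and ensemble change statistics
    with multiple-regression attribution of yield, evapotranspiration and
    water-use-efficiency changes to climate drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
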