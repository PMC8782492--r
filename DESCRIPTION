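Package: greenwave
Title: Streamflow and Temperature Phenology Models of Ungulate Spring Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links the timing of the snowmelt spring pulse in daily streamflow
    records and temperature-derived plant-phenology metrics (cumulative growing
    degree day, the GDD-180 day, and the sigmoid third-derivative "jerk" day) to
    the onset of spring migration in mule deer herds. Provides readers for USGS
    daily-values RDB and plain CSV series, the Cayan cumulative-departure
    spring-pulse detector, Kendall-Theil/Mann-Kendall trend tests with an
    autocorrelation pre-check, a Bayesian Bernoulli-logit migration model fit by
    MCMC with DIC and posterior-predictive recall/precision scoring, a daily
    probability-of-migration predictor, and synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    coda,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
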