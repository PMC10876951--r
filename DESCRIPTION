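Package: firescape
Title: Forest Disturbance Mapping, Agent Attribution and Fire Hazard
    Analysis for War-Affected Landscapes
Version: 0.1.0
Authors@R:
    person("firescape", "developers", email = "firescape@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping abrupt forest damage from annual spectral-index
    trajectories and before/after composite differencing, attributing
    disturbance agents (stand-replacing fire, stand-replacing harvest,
    non-stand-replacing) from spectral and landscape-shape features,
    quantifying elevated future fire hazard from land-cover adjacency,
    design-based stratified area estimation with standard errors, and
    fire-weather anomaly detection. Ships a synthetic-landscape generator so
    the full pipeline runs end-to-end without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
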