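Package: bmhvflow
Title: Pulsatile Hemodynamics and Doppler Criteria for Dysfunctional
    Bileaflet Mechanical Heart Valves with Subaortic Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale in-silico pipeline for blood flow through a
    bileaflet mechanical heart valve (BMHV) with concomitant tunnel-type
    subaortic stenosis. Builds parametric 2D outflow-tract geometries,
    advances pulsatile incompressible flow with a masked-cell projection
    method (optional k-omega eddy-viscosity closure), post-processes
    vorticity and shear-stress fields, extracts clinical Doppler
    surrogates (peak velocity, mean transvalvular gradient, Doppler
    velocity index, effective orifice area) and evaluates the sensitivity
    and specificity of guideline thresholds for valve dysfunction over a
    45-case study grid of outflow-tract diameter, leaflet dysfunction and
    cardiac output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
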