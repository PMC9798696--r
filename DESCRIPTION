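Package: pseudotrack
Title: Pseudo-Absence Null Movement Models for Environmental Selection in
    Animal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing environmental selection in marine animal
    telemetry tracks against pseudo-absences generated by environmentally
    naive null movement models.  Implements four null simulators (Brownian
    motion with lognormal steps, truncated Levy flight, correlated random
    walk, and joint correlated random walk) restarted at the observed animal
    position at the start of each calendar month; a Von Mises biased random
    walk that generates synthetic presence tracks with a prescribed strength
    of selection for warm sea-surface temperature; uncertainty-weighted
    matching of positions to gridded SST fields; one-sided two-sample
    Kolmogorov-Smirnov tests for warmer or colder selection; and a
    simulation harness that measures power and false-positive rates as a
    function of selection strength, aggregated tracking time, and the
    significance threshold.  A synthetic SST-field generator with a
    meridional gradient, mesoscale anomalies, a seasonal cycle, and clumped
    missingness makes the whole pipeline testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr
Config/testthat/edition: 3
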