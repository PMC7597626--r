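Package: photodiurnal
Title: Diurnal Dynamics of Leaf Gas Exchange Under Drought and Silicon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a log-linear time-course model of diurnal leaf gas
    exchange, p(t) = exp(omega*ln(t) - eta/t + psi), to photosynthesis,
    stomatal-conductance and transpiration series measured through the
    day; computes goodness-of-fit statistics, cumulative and daily
    totals by numerical quadrature, and treatment comparisons (percent
    gain, per-time one-way ANOVA) for factorial water-stress x silicon
    experiments. A synthetic-data module simulates the full factorial
    experiment, including diurnal microclimate profiles, so the whole
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
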