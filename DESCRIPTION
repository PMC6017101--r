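Package: combindex
Title: Median-Effect Dose-Response Analysis and Drug-Combination Synergy
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies two-drug combination effects from enzyme-inhibition
    dose-response data using the Chou-Talalay median-effect principle.
    Converts raw colorimetric kinetic traces to percent inhibition, fits the
    median-effect equation fa/fu = (D/Dm)^m by least squares on the log-log
    (median-effect plot) scale, builds constant-ratio combination designs at
    IC50 multiples, and computes combination-index (CI) profiles and
    dose-reduction-index (DRI) tables with synergy/additivity/antagonism
    classification under Loewe additivity. Includes a seeded synthetic
    dose-effect generator with a controllable true combination index, so
    the whole pipeline is testable without experimental data, plus tidy()
    and glance() methods, ggplot2 figures, and a JSON/CSV report writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
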