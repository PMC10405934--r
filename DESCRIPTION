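Package: crlmcea
Title: Cost-Effectiveness Modelling of Imaging Strategies for Resectable
    Colorectal Liver Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of diagnostic imaging strategies
    (contrast-enhanced CT, MRI and 18F-FDG PET/CT) for detecting colorectal
    liver metastases eligible for hepatic resection. A diagnostic decision
    tree feeds a five-state annual-cycle Markov cohort model with
    age-dependent background mortality from a life table; the package
    computes discounted costs and quality-adjusted life years per strategy,
    incremental cost-effectiveness ratios with dominance and efficiency
    frontier ranking, net monetary benefit, deterministic one-way (tornado)
    and two-way sensitivity analyses, and Monte Carlo probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves. An
    individual-level microsimulation oracle and synthetic parameter and
    life-table generators support validation of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
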