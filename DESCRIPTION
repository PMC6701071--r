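Package: smokedyn
Title: System-Dynamics Simulation of Adolescent Smoking and Tobacco Control Policies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of youth smoking in a
    two-cohort aging chain with social-pressure, secondhand-smoke, risk
    perception and price feedback loops. Includes a fixed-step Euler
    integration engine, bounded least-squares calibration to historical
    past-30-day smoking prevalence, one-at-a-time sensitivity analysis that
    separates level change from behaviour-mode change, step-change policy
    experiments (excise tax, comprehensive tobacco control programme funding,
    retailer compliance), and a synthetic-data generator so the whole
    pipeline runs reproducibly from a single seed.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
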