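Package: msnpkill
Title: Tumor Kill-Fraction Modelling from Nanoparticle Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links mesoporous silica nanoparticle (MSNP) accumulation in
    tumors, quantified as elemental silicon mass percent, to chemotherapy
    efficacy in preclinical tumor volume studies. Computes kill-fraction
    time courses from treated and control growth curves, fits the
    quadratic response law f_kill = theta_f * (t - t0)^2 per subject with
    onset-day optimization, fits the exponential uptake-response law
    theta_f = A * exp(B * Si) across subjects by nonlinear least squares,
    and supports graphite furnace atomic absorption (GFAA)
    standard-additions silicon quantification and delivery-efficiency
    (percent injected dose) calculations. Includes a synthetic cohort
    generator with known ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
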