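Package: xenopkpd
Title: Pharmacokinetic/Pharmacodynamic Modeling of Tumor Growth Inhibition in Xenograft Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential pharmacokinetic/pharmacodynamic (PK/PD) analysis of an
    EGFR tyrosine-kinase inhibitor given alone or with an herbal adjuvant in a
    tumor xenograft mouse study. Provides a one-compartment oral PK model with
    multiple-dose superposition, noncompartmental exposure metrics (AUC, Cmax)
    with a nonparametric two-group comparison, the Simeoni tumor-growth-inhibition
    model with three transit death compartments and a combination synergy factor,
    likelihood-based estimation (Laplace marginal likelihood for the PK
    mixed-effects model, pooled maximum likelihood for the tumor model), visual
    predictive checks, model-based simulation of time to a tumor-volume
    threshold, and a synthetic-data generator emulating the study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
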