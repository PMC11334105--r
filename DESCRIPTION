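Package: covkin
Title: Two-Step Covalent Inhibition Kinetics and Transition-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects covalent inhibitor potency into noncovalent recognition
    and warhead reactivity for KRAS G12C switch II pocket inhibitors. Fits the
    two-step irreversible binding model to mass-spectrometry target-occupancy
    time courses (one-phase association to k_obs, hyperbolic k_obs-concentration
    regression to K_I and k_inact), corrects glutathione surrogate reactivity
    for aqueous degradation (k_app = k_deg + k_GSH), fits single-exponential
    nucleotide-exchange traces and four-parameter log-logistic dose-response
    curves, and converts the resulting rates to free energies via RT ln(K_I)
    and the Eyring transition-state relation with a Henderson-Hasselbalch
    thiolate correction for glutathione. Includes seeded synthetic-data
    generators emulating each assay design, a mass-action ODE cross-check of
    the rapid-equilibrium approximation, and publication-style table reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
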