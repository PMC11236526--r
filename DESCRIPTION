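Package: csfdyn
Title: Gas-Challenge BOLD Modeling of Cerebrovascular Response Dynamics
    and CSF Inflow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse blood oxygen level-dependent
    (BOLD) fMRI experiments with controlled hypercapnic and hyperoxic
    respiratory challenges.  Provides a forward model for end-tidal gas
    protocols and the coupled BOLD/cerebrospinal-fluid (CSF) inflow signal,
    estimation of the vascular response time constant tau by least-squares
    fitting against the end-tidal CO2 trace convolved with an exponential
    hemodynamic response function, skew-normal characterisation of CSF
    inflow peaks with right-sided half width at half maximum, shifted
    cross-correlation lag estimation between inflow and vascular signals,
    wavelet de-noising with the universal hard threshold, and cohort-level
    regressions of tau against inflow width and edema load.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
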