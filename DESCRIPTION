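Package: starGC
Title: In Silico Glycaemic Control and Nutrition Delivery with the STAR Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual-patient toolkit for model-based intensive-care glycaemic
    control in the style of the STAR (Stochastic TARgeted) protocol. Provides a
    glucose-insulin pharmacokinetic/pharmacodynamic model with saturable insulin
    action and a fixed-step Runge-Kutta simulator, integral-based identification
    of model-based insulin sensitivity from blood-glucose measurements, kernel
    conditional-density forecasting of hour-scale insulin-sensitivity
    variability, risk-bounded joint insulin and enteral-nutrition dosing with a
    5% hypoglycaemia constraint, patient-specific daily caloric-goal
    calculation, per-ICU-day nutrition-delivery analytics, and a synthetic
    virtual-patient cohort generator for closed-loop in-silico trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
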