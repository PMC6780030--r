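Package: emwtrials
Title: Human In Silico Drug Trials with the Cellular Electromechanical Window
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: In silico drug trials in experimentally calibrated populations of
    human ventricular action-potential models (O'Hara-Rudy dynamic model,
    endocardial variant). Provides conductance-scaled model populations paced
    to steady state and calibrated against experimental action potential and
    calcium transient biomarker ranges, IC50/Hill pore-block drug simulation
    at multiples of the therapeutic concentration, extraction of the cellular
    electromechanical window (EMw = CTD90 - APD90), automatic detection of
    repolarisation and depolarisation abnormalities, Torsade-de-Pointes risk
    classification and concentration-weighted risk scores, and an exhaustive
    IKr/ICaL/INaL block-grid sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
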