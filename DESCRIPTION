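Package: cocktailpbpk
Title: Physiologically Based Pharmacokinetic Analysis of a Six-Drug Cocktail in Cirrhotic and Healthy Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Reduced physiologically based pharmacokinetic (PBPK) models of a
    six-drug phenotyping cocktail (caffeine, codeine, midazolam, torsemide,
    pravastatin, talinolol) and their phase-I/phase-II metabolites in mice,
    together with cirrhosis perturbation rules, structural hypothesis variants
    for altered glucuronide disposition (increased UGT activity, reduced
    biliary clearance, increased sinusoidal export), multi-start least-squares
    parameter estimation, pharmacokinetic summary metrics, a synthetic cohort
    generator with lognormal measurement noise and inter-animal variability,
    and cross-species differential-expression comparison utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
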