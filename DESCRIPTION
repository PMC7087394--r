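Package: mrphewas
Title: Mendelian Randomization Phenome-Wide Scans with Genetic Risk Score
    Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hypothesis-free Mendelian randomization phenome-wide
    association scans (MR-pheWAS) built around a weighted genetic risk score
    instrument, modelled on the design used to screen age at menarche against
    a biobank phenome. Provides a synthetic cohort generator with explicit
    horizontal- and vertical-pleiotropy paths through body mass index,
    construction of filtered instrument sets (Steiger filtering and proximity
    exclusion around competing-trait loci), a rule-based phenome scan with
    regression dispatch by trait type and rank-based FDR/Bonferroni
    thresholding, the standard two-sample and one-sample Mendelian
    randomization estimator suite (Wald ratios, fixed/random-effects IVW,
    MR-Egger, weighted median, mode-based estimators, MR-PRESSO, two-stage
    least squares with bootstrap standard errors, multivariable MR), and
    analytic power calculations for replication designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
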