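Package: fanovarm
Title: Two-Way Functional ANOVA with Repeated Measures by Basis Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hypothesis testing for functional data observed under a two-way
    repeated-measures design: each subject, belonging to one of several
    independent groups, contributes one curve per treatment condition. Sample
    curves are projected onto a finite basis (cubic B-splines by default) and
    the treatment, group and interaction (parallelism) hypotheses are tested
    on the basis coefficients with the Doubly Multivariate Model (MANOVA on
    the stacked per-treatment coefficients), the Mixed Multivariate Model
    (with a multivariate-sphericity likelihood-ratio test and a Box-type
    degrees-of-freedom correction), and a repeated-measures permutation
    procedure. A simulation engine generates curve data under configurable
    treatment/group/interaction effect functions with Gaussian or Brownian
    errors and runs size/power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
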