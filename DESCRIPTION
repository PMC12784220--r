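Package: brainprofiles
Title: Brain Activation Modules, Latent Activity Profiles, and
    Continuous-Report Memory Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering latent structure in cohort task-fMRI
    activation tables and continuous-report visual short-term memory data.
    Detects modules of regions with similar inter-individual variability via
    consensus Louvain community detection on inter-subject correlation
    networks with a resolution sweep selected by adjusted mutual information;
    residualizes a global responsivity factor from module activity; discovers
    participant subgroups with constrained diagonal-covariance Gaussian
    mixtures (latent profile analysis) selected by BIC, ICL and a parametric
    bootstrap likelihood-ratio test; fits the three-component von Mises
    mixture model of continuous-report response errors (target, non-target
    misbinding, uniform guessing); and provides the accompanying statistics
    layer: Welch heteroscedastic ANOVA and t-tests, chi-squared tests,
    Benjamini-Hochberg FDR, default-prior Bayes factors for t-tests, one-way
    ANOVA and correlations, Bayesian R-squared, age-adjusted partial
    correlations with Fisher z comparisons, and power analysis for
    correlation tests. A synthetic-cohort generator with planted modules,
    subgroups and behavioural parameters provides ground truth for every
    stage, and a pipeline driver runs the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
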