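Package: mrflow
Title: Two-Sample Mendelian Randomisation from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation with GWAS summary
    statistics: reading and harmonising per-SNP association tables with
    proxy-SNP substitution, construction of pleiotropy-filtered instrument
    sets, five causal-effect estimators (inverse-variance weighted with
    multiplicative random effects, MR-Egger with intercept test, weighted
    median, weighted mode, penalised robust IVW), Cochran's Q heterogeneity
    and regression-influence diagnostics with stepwise instrument pruning,
    multivariable MR with its Egger extension, instrument-strength and
    binary-outcome power analytics, and a synthetic summary-statistics
    generator with known causal truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
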