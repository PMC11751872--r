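Package: genmodmeta
Title: Genetic-Model Selection for SNP Association Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combined evaluation of candidate-gene case-control studies of a
    biallelic SNP: Hardy-Weinberg screening and quality-based inclusion
    filters; per-study odds ratios under six genetic models (allelic,
    homozygote, heterozygote, dominant, recessive, over-dominant);
    fixed-effect and DerSimonian-Laird random-effects pooling with a
    heterogeneity-driven switching rule, leave-one-out, subgroup,
    meta-regression and publication-bias diagnostics; Bayesian random-effects
    network meta-analysis over genotype nodes with SUCRA ranking of genetic
    models; Thakkinstian's algorithm for inheritance-model selection; false
    positive report probability (FPRP) noteworthiness; a composite
    candidate-to-definitive decision rule; and a diagnostic-accuracy
    meta-analysis (Moses-Littenberg SROC with AUC) of risk-genotype
    dichotomizations. Includes a case-control genotype simulator with known
    generative truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    metafor,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
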