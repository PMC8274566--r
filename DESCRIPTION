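Package: earlygs
Title: Genomic Selection for Early-Stage Testcross Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage genomic-selection analysis for early-stage maize
    breeding programs evaluating doubled-haploid testcrosses under
    well-watered and managed drought conditions. Stage one fits the
    per-environment phenotypic mixed model (adjusted genotype means,
    variance components, entry-mean broad-sense heritability); stage two
    builds a genomic relationship matrix from dominant presence/absence
    markers and fits a reaction-norm GBLUP with a genomic main effect and
    a Hadamard-product genotype-by-environment kernel, by REML or Gibbs
    sampling. A forward cross-validation engine implements year-to-year
    prediction schemes with fractional conversion of the testing set into
    the training set, and a breeding-program simulator generates marker,
    pedigree and multi-environment trial data with known ground truth so
    every stage can be tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
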