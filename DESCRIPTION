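Package: threewii
Title: Entropy-Based Three-Way Interaction Prioritization for Case-Control SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes third-order (three-way) SNP interactions in case-control
    genotype studies. Implements the basic allelic chi-square association filter,
    two-step random-forest feature selection with permutation-importance p-values,
    plug-in entropy estimators for two-way mutual information and three-way
    interaction information, case-versus-control information-gain test statistics
    with a delta-method variance normalizer referred to a chi-square distribution
    with one degree of freedom, linkage-disequilibrium and pairwise-signal
    exclusion filters, and label-shuffling permutation validation. Includes a
    synthetic cohort generator that plants penetrance-table triplets whose
    association is purely third-order, plus PLINK 1 binary (BED/BIM/FAM) input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
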