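Package: snpgrs
Title: Case-Control SNP Association and Weighted Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-SNP case-control studies of complex traits:
    per-SNP quality control (call rate, minor-allele frequency,
    Hardy-Weinberg goodness-of-fit in controls), additive-model logistic
    association on grouped genotype counts with a dominance-deviation
    (DOMDEV) test and Bonferroni significance handling, pairwise linkage
    disequilibrium from unphased genotypes via two-locus EM haplotype
    estimation (Lewontin D-prime, r-squared, bootstrap confidence
    intervals, Gabriel-style haplotype blocks, D-prime threshold pruning),
    and weighted genetic risk scores with quartile odds ratios and the
    Cochran-Armitage trend test.  A seeded synthetic-cohort generator and
    packaged reference count tables make every stage testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
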