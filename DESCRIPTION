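Package: ancestrees
Title: Ancestry Classification from SNP Genotypes with Ensembles of
    Disjoint Decision Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns ensembles of disjoint CART-style decision trees that
    predict continental or sub-continental ancestry from SNP genotype
    calls. Trees are trained sequentially, each on the SNP pool minus all
    SNPs used by earlier trees, so a subject with missing genotypes loses
    only the trees touching a missing SNP: every remaining tree still
    votes, and the majority over voting trees is the predicted ancestry
    together with a population-inclusion probability vector. Includes the
    SNP quality filters (call rate, chromosome, Hardy-Weinberg
    equilibrium), the binomial sizing mathematics that chooses the number
    of trees needed for a target confidence under per-SNP missingness,
    stratified k-fold cross-validation, genomic-control lambda assessment
    for case-control cohorts, and a Balding-Nichols genotype simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
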