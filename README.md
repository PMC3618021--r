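# ancestrees

Ancestry classification from SNP genotypes with ensembles of
**disjoint** decision trees, and classifier-based correction of
population stratification in case–control association studies.

## The problem and who this is for

Genome-wide association studies are confounded when cases and controls
are sampled unevenly from ancestrally distinct subpopulations: SNPs
whose allele frequencies differ between those subpopulations then show
spurious phenotype associations, visible as an inflated genomic-control
factor λ (the median per-SNP 1-df χ² statistic divided by its null
median, 0.4549364). `ancestrees` is for analysts who want to *classify*
each subject's ancestry from a small SNP panel — robustly to missing
genotype calls — and restrict their association analysis to an
ancestrally homogeneous subset.

## The method

Trees are CART classifiers over the four-symbol genotype alphabet
`A_A / A_B / B_B / NoCall`, with binary splits over the three
bipartitions of the called genotypes. The ensemble is built
sequentially: each tree is learned on the SNP pool minus every SNP used
by earlier trees, so the trees' SNP sets are pairwise disjoint. A tree
votes for a subject only if *all* of its SNPs are called, and abstains
otherwise; the prediction is the majority over voting trees, together
with an inclusion-probability vector (votes divided by voting trees —
15, 4 and 8 votes with 2 abstentions among 29 trees give
15/27, 4/27, 8/27).

Disjointness is what buys robustness to missingness, and it can be
sized analytically. With per-SNP NoCall probability *u* and an average
of *n* SNPs per tree, a tree is fully observed with probability
p = (1 − u)ⁿ, and the confidence of at least *m* clean trees among *N*
is the upper binomial tail

    C(N, m, p) = 100 · (1 − Σ_{i=0}^{m−1} C(N, i) pⁱ (1 − p)^{N−i}).

Choosing *m* as the smallest sub-ensemble size whose cross-validated
majority-vote accuracy reaches the accuracy target, the recommended
ensemble size is the smallest *N* whose confidence reaches the
confidence target. With p = 0.59049 (u = 0.1 at roughly five SNPs per
tree) and m = 9, a 99.9% confidence target gives N = 29.

The package also provides the standard SNP quality filters (100% call
rate, autosomes only, Hardy–Weinberg equilibrium by Pearson χ²),
stratified k-fold cross-validation, the Cochran–Armitage trend scan
with genomic-control λ, and a Balding–Nichols population simulator so
the whole pipeline is testable without external genotype data.

## Worked example

```r
library(ancestrees)

# three diverged populations, 60 samples each, 500 SNPs
sim <- simulate_populations(3, 60, 500, fst = 0.15, seed = 7)
flt <- filter_snps(sim$genotypes, sim$labels)
flt$report
#> SNP filter report
#>   Total SNPs                         500
#>   SNPs with call rate < 100%         0
#>   SNPs on X/Y/MT/unknown chromosome  0
#>   SNPs deviating from HWE            61
#>   Filtered SNPs (union)              61
#>   Unfiltered SNPs                    439

ens <- train_ensemble(flt$matrix, sim$labels, n_trees = 5,
                      params = tree_params(seed = 7))
ens
#> disjoint_ensemble: 5 trees over 20 SNPs ( POP1, POP2, POP3 )
#>   SNPs per tree: 3, 4, 4, 4, 5

tree_to_rules(ens$trees[[1]])
#> IF snp306 in {A_A} AND snp123 in {A_A} THEN population = POP3
#> IF snp306 in {A_A} AND snp123 in {A_B, B_B} THEN population = POP2
#> IF snp306 in {A_B, B_B} AND snp409 in {B_B} THEN population = POP3
#> IF snp306 in {A_B, B_B} AND snp409 in {A_A, A_B} THEN population = POP1

# knock out the first tree's SNPs: it abstains, the other four still vote
s <- flt$matrix$calls[1, ]
s[ens$trees[[1]]$snp_set] <- NA_integer_
predict(ens, s)
#> vote_prediction: label = POP1
#>   votes: POP1=4, POP2=0, POP3=0 | abstained: 1
#>   prob:  POP1=1.0000, POP2=0.0000, POP3=0.0000

# how many trees would this panel need at a 10% NoCall rate, if
# 3 voting trees suffice for the accuracy target?
build_plan(ens, cv_report = NULL, u = 0.1, acc_target = 99.9,
           conf_target = 99.9, m = 3)
#> robustness_plan
#>   per-SNP NoCall probability u      0.1
#>   average SNPs per tree n           4
#>   per-tree coverage p = (1-u)^n     0.65610 (q = 0.34390)
#>   minimal accurate sub-ensemble m   3 (target 99.9%)
#>   recommended trees N               12 (confidence 99.93% target 99.9%)
```

The filter report reads as a QC table: 61 of 500 simulated SNPs
deviate from Hardy–Weinberg within at least one population at the
nominal 0.05 level and are removed. The five trained trees use 20 SNPs
in total, all distinct. Masking one tree's SNPs costs exactly one vote,
and the sizing plan converts the panel's own geometry (n = 4 SNPs per
tree) into a recommended ensemble size.

For a stratified case–control cohort,
`stratification_correction_experiment()` computes λ before and after
excluding subjects that the classifier does not place in the target
population — on a two-population cohort with case fractions (0.8, 0.2)
the trend-scan λ drops from far above 1 to about 1.

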