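---
title: "Ancestry classification with ensembles of disjoint decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry classification with ensembles of disjoint decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestrees)
```

## The problem

Case–control genome-wide association studies are confounded when cases
and controls are drawn unevenly from ancestrally distinct
subpopulations: any SNP whose allele frequencies differ between the
subpopulations then shows a spurious association with the phenotype.
The classical diagnostic is the genomic-control inflation factor
$\lambda$, the median per-SNP 1-df $\chi^2$ association statistic
divided by its theoretical null median (0.4549364); $\lambda \approx 1$
indicates an unstratified cohort.

`ancestrees` addresses the stratification problem by *classifying* each
subject's ancestry directly from a small panel of SNP genotypes, so
that an association analysis can be restricted to an ancestrally
homogeneous subset. The classifier is an ensemble of CART-style
decision trees with one distinctive structural property: the trees use
**pairwise-disjoint SNP sets**. Trees are learned sequentially — the
first on the full SNP pool, each later tree on the pool minus every SNP
used by earlier trees. Disjointness is what makes the ensemble robust
to missing genotypes: a failed call (NoCall) silences at most the
single tree that uses that SNP, and every other tree still votes.

## The model

### Genotype representation

A SNP genotype is one of four symbols: major homozygote (`A_A`),
heterozygote (`A_B`), minor homozygote (`B_B`), or `NoCall`. The model
stores each SNP's actual allele characters, so "major" is a label for a
stored allele pair rather than a dataset-relative code; at prediction
time genotypes are matched as unordered allele pairs and cannot flip
meaning across datasets.

### SNP quality control

`filter_snps()` removes a SNP when (a) any sample has a NoCall for it,
(b) it lies on the X or Y chromosome, the mitochondrial genome, or an
unknown chromosome, or (c) its genotype counts deviate from
Hardy–Weinberg equilibrium (Pearson $\chi^2$, 1 df, no continuity
correction, nominal $p < 0.05$). Criteria are flagged independently and
the union is removed, so the filter report shows per-criterion counts
whose sum may exceed the union.

The HWE test defaults to *per-population* testing (a SNP is flagged if
it deviates within any labelled population). Testing pooled samples
instead would flag exactly the ancestry-informative SNPs the classifier
needs, because mixing populations with different allele frequencies
produces an apparent heterozygote deficit (the Wahlund effect) at
precisely those SNPs. Pooled testing remains available as an explicit
option for replaying analyses where labels are absent.

### Tree learning

`learn_tree()` is a CART learner specialised to the three-level
genotype alphabet. Every split is one of the three bipartitions of
$\{A\_A, A\_B, B\_B\}$ — $\{A\_A\}$ vs the rest (dominant),
$\{A\_B\}$ vs the rest (heterozygote-specific), $\{B\_B\}$ vs the rest
(recessive) — evaluated by Gini impurity decrease. Growth stops at node
purity, at the minimum leaf size (default 5 samples), or when no split
strictly decreases impurity. By default the grown tree is pruned by
cost-complexity pruning with the 1-SE rule over an internal stratified
10-fold cross-validation, the classical CART recipe; `prune = "none"`
is available for controlled experiments.

Two deterministic tie-breaks make training reproducible and invariant
to SNP column permutations: equal-quality splits resolve to the SNP
earliest in matrix column order and then to the bipartition listing
order above, and equal leaf class counts resolve to the earliest class
in `class_order`. Zero-variance SNPs are excluded from candidate
splits, and single-class training input yields a legal single-leaf tree
(with a warning) rather than an error, so cross-validation folds with
accidental class absence still run.

### Abstention and voting

A tree votes for a subject only when *every* SNP the tree uses is
called — not merely the SNPs on the realized root-to-leaf path.
This whole-tree rule is the default because the ensemble's sizing
mathematics below assumes a tree is usable exactly when all of its
SNPs are present; a path-only mode exists
(`predict_tree(..., require_all_snps = FALSE)`) but is off by default.
The ensemble prediction divides each class's votes by the number of
*voting* trees: 15, 4 and 8 votes with 2 abstentions among 29 trees
give the inclusion-probability vector $(15/27,\, 4/27,\, 8/27)$, and
the label is the class with the most votes (ties are flagged and broken
by class order; a subject on whom every tree abstains is labelled
`NO_CALL`). `apply_inclusion_cutoff()` turns these vectors into a
sample-exclusion rule for downstream association analyses.

## Sizing the ensemble against missingness

Let $u$ be the per-SNP NoCall probability (NoCalls assumed independent
across SNPs) and $n$ the average number of SNPs per tree. A tree is
fully observed with probability

$$p = (1-u)^n,$$

so the number of clean trees among $N$ is $\mathrm{Binomial}(N, p)$
and the confidence of having at least $m$ clean trees is the upper
binomial tail

$$C(N, m, p) = 100 \times \Bigl(1 - \sum_{i=0}^{m-1}
  \binom{N}{i} p^i (1-p)^{N-i}\Bigr).$$

Note the sum starts at $i = 0$: at $N = m$ the formula must reduce to
$100\,p^m$ (all trees clean), which anchors the whole confidence table.
`ensemble_confidence()` evaluates this via the exact binomial tail;
`min_trees_for_confidence()` scans for the smallest $N$ reaching a
target confidence.

The remaining ingredient is $m$, the smallest sub-ensemble size whose
average majority-vote accuracy reaches the accuracy target.
`min_ensemble_size_for_accuracy()` estimates, for each size $s$, the
average cross-validated accuracy over size-$s$ tree subsets —
exhaustively while $\binom{T}{s} \le 10^5$, otherwise over $10^5$
seeded random subsets (both caps configurable). Out-of-fold
predictions are used throughout so the size–accuracy table is not
optimistically biased. `build_plan()` chains the four steps
($n \to p \to m \to N$) and records every intermediate symbol; it also
accepts a directly quoted $p$ or $m$ so that a published sizing
analysis can be replayed exactly — with $p = 0.59049$, $m = 9$ and a
99.9% confidence target the recommended size is $N = 29$.

## Evaluation

`kfold_cv()` runs stratified, seeded k-fold cross-validation (default
$k = 10$): each fold trains a fresh disjoint ensemble on the other
folds and scores the held-out fold, reporting per-tree accuracy and the
cumulative accuracy of the first $j$ trees as mean ± sd over folds.
Held-out subjects are scored with abstention allowed, and an
all-abstain `NO_CALL` ensemble prediction counts as an error. Fold
assignment staggers class round-robins so per-fold class proportions
stay within one sample of the global proportions.

The association scan uses the Cochran–Armitage trend statistic with
scores $(0, 1, 2)$ — the GWAS standard 1-df test — with an allelic
$2\times2$ $\chi^2$ available as an option; `genomic_lambda()` divides
the median statistic by 0.4549364. The end-to-end demonstration
`stratification_correction_experiment()` computes $\lambda$ before and
after classifier-based sample exclusion.

## The synthetic-data generator

Real reference panels are large downloads, so the package carries a
Balding–Nichols generator that every module is tested against. Each
SNP draws an ancestral frequency $\pi \sim \mathrm{Uniform}(0.1, 0.9)$;
population $k$ draws its own frequency from
$\mathrm{Beta}\bigl(\pi\tfrac{1-F}{F},\,(1-\pi)\tfrac{1-F}{F}\bigr)$,
whose mean is $\pi$ and whose divergence grows with $F$ (the $F_{ST}$
parameter); genotypes are $\mathrm{Binomial}(2, \cdot)$ draws,
independently masked to NoCall with probability $u$.
`simulate_case_control()` adds a phenotype drawn per sample from its
population's case fraction, with **no** genotype–phenotype effect, so
all downstream association signal is pure stratification. The
generator returns the true per-population frequencies so tests can
check its own marginals (Hardy–Weinberg proportions at the true
frequency).

What the generator deliberately omits — and what passing tests
therefore do not establish about real cohorts — is linkage
disequilibrium between SNPs, admixed individuals, genotyping batch
effects, and non-independent missingness. Divergence between real
continental populations ($F_{ST} \approx 0.1$–$0.15$) is emulated
directly; sub-continental problems correspond to smaller $F$ and
need more SNPs or more trees for comparable accuracy.

## Study conditions used by the test suite

The package's heavier checks fix these conditions once:

* *Classification recovery*: 3 populations, $F = 0.15$, 200 samples per
  population, 1000 SNPs, no training-time missingness; a stratified 2/3
  vs 1/3 train/test split; a 3-tree ensemble must reach 95% held-out
  accuracy, and a 29-tree ensemble evaluated with $u = 0.1$
  prediction-time masking must produce `NO_CALL` for fewer than 1% of
  subjects.
* *Stratification demonstration*: 2 populations, $F = 0.1$, 300 samples
  per population, 2000 SNPs, case fractions $(0.8, 0.2)$; the trend
  scan's $\lambda$ must exceed 1.1 before exclusion and decrease after
  restricting to subjects classified into the first population at
  cut-off 0.5 (a 5-tree classifier is ample at this divergence).
* *Null calibration*: one panmictic population, $10^4$ SNPs, case
  fraction 0.5; $\lambda$ must land in $[0.9, 1.1]$.

These sizes were chosen as realistic small-cohort analogues of
reference-panel studies and are not tuned to any particular outcome.

## Numerical choices and edge cases

* Split acceptance requires a Gini decrease above $10^{-12}$;
  candidate splits within $10^{-10}$ of the best are treated as tied
  and resolved by the deterministic ordering.
* Monomorphic genotype counts give an HWE $\chi^2$ of 0 and $p = 1$:
  a monomorphic SNP is never HWE-flagged, and the tree learner ignores
  it as zero-variance.
* The binomial tail is computed by `stats::pbinom`, not by summing
  binomial coefficients, so it is stable for large $N$.
* `train_ensemble()` raises an error naming the number of completed
  trees when the informative SNP pool is exhausted before the requested
  count.
* Model files are version-tagged JSON; loading verifies the format
  version and reconstructs the ensemble bit-exactly, including the
  training parameters and seed.

## Known limitations

Greedy CART can miss purely epistatic (interaction-only) signals whose
marginal effects vanish; the ensemble inherits this. Vote probabilities
are crude ancestry summaries, not admixture fractions. The sizing
mathematics assumes NoCalls independent across SNPs with a common rate
$u$; clustered assay failures violate this and make the confidence
estimates optimistic. Finally, per-tree coverage uses the *average*
SNPs per tree; trees larger than average are individually more fragile
than $p$ suggests.
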