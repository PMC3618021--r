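# Evaluation: stratified k-fold cross-validation of trees and cumulative
# ensembles, confusion/agreement statistics, per-SNP case-control
# association scan, and the genomic-control inflation factor lambda.

# theoretical median of the chi-squared distribution with 1 df
CHI2_1DF_NULL_MEDIAN <- 0.4549364

#' Stratified k-fold cross-validation of a disjoint-tree ensemble
#'
#' Partitions the samples into `k` stratified folds (seeded). For each
#' fold, a fresh disjoint ensemble of `n_trees` trees is trained on the
#' other k-1 folds and evaluated on the held-out fold: per-tree accuracy
#' and the cumulative majority-vote accuracy of the first j trees, for
#' j = 1..n_trees. Accuracies are aggregated as mean and standard
#' deviation over the k folds. Held-out subjects are scored with
#' abstention allowed; an ensemble prediction of `"NO_CALL"` (every tree
#' abstained) counts as incorrect.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param labels A [population_labels()].
#' @param k Fold count (default 10).
#' @param n_trees Trees per fold ensemble.
#' @param params A [tree_params()].
#' @param seed Seed for the fold assignment.
#' @return A list of class `cv_report`: `k`, `fold_assignment` (named
#'   integer), `per_tree_acc` and `cumulative_acc` (data frames with
#'   mean/sd in percent), `out_of_fold_predictions` (trees x samples
#'   character matrix, `NA` = abstained), `truth` and `class_order`.
#' @export
kfold_cv <- function(gm, labels, k = 10L, n_trees, params = tree_params(),
                     seed = 1L) {
  validate_genotype_matrix(gm)
  y <- label_factor(labels, gm)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(y)) stop("k exceeds the sample count")
  counts <- table(y)
  if (any(counts > 0 & counts < k)) {
    warning("some classes have fewer than k members; folds may miss classes")
  }
  fold <- stratified_folds(y, k, seed = seed)
  names(fold) <- sample_ids(gm)
  n_trees <- as.integer(n_trees)

  n_samp <- length(y)
  oof <- matrix(NA_character_, nrow = n_trees, ncol = n_samp,
                dimnames = list(NULL, sample_ids(gm)))
  per_tree <- matrix(NA_real_, nrow = k, ncol = n_trees)
  cumulative <- matrix(NA_real_, nrow = k, ncol = n_trees)
  truth <- as.character(y)

  for (f in seq_len(k)) {
    tr <- fold != f
    te <- which(!tr)
    fold_params <- params
    fold_params$seed <- params$seed + f
    ens <- train_ensemble(subset_genotypes(gm, samples = which(tr)),
                          labels, n_trees = n_trees, params = fold_params)
    used <- ensemble_snps(ens)
    test_calls <- gm$calls[te, used, drop = FALSE]
    votes <- matrix(NA_character_, nrow = n_trees, ncol = length(te))
    for (j in seq_len(n_trees)) {
      votes[j, ] <- vapply(seq_along(te), function(i) {
        predict_tree(ens$trees[[j]], row_named(test_calls, i))
      }, character(1))
    }
    oof[, te] <- votes
    for (j in seq_len(n_trees)) {
      per_tree[f, j] <- 100 * mean(!is.na(votes[j, ]) & votes[j, ] == truth[te])
      labels_j <- vapply(seq_along(te), function(i) {
        tally_votes(votes[seq_len(j), i], labels$class_order)$label
      }, character(1))
      cumulative[f, j] <- 100 * mean(labels_j == truth[te])
    }
  }

  agg <- function(mat) {
    data.frame(index = seq_len(ncol(mat)),
               mean = colMeans(mat),
               sd = apply(mat, 2L, stats::sd))
  }
  structure(list(
    k = k,
    fold_assignment = fold,
    per_tree_acc = agg(per_tree),
    cumulative_acc = agg(cumulative),
    out_of_fold_predictions = oof,
    truth = truth,
    class_order = labels$class_order
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", x$k, "folds,", nrow(x$out_of_fold_predictions), "trees\n")
  last <- nrow(x$cumulative_acc)
  cat(sprintf("  full-ensemble CV accuracy: %.2f%% +/- %.2f%%\n",
              x$cumulative_acc$mean[last], x$cumulative_acc$sd[last]))
  invisible(x)
}

#' Percent agreement of a confusion table
#'
#' @param confusion A square matrix or table of counts; rows and columns
#'   in matching class order.
#' @return `100 * sum(diag) / sum(all)`, in percent.
#' @export
percent_agreement <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion table must be square")
  if (any(confusion < 0)) stop("counts must be non-negative")
  total <- sum(confusion)
  if (total < 1) stop("confusion table is empty")
  100 * sum(diag(confusion)) / total
}

#' Cochran-Armitage trend chi-squared statistic (1 df)
#'
#' Tests for a linear trend in case proportion across the three genotype
#' classes with scores (0, 1, 2) — the standard per-SNP GWAS association
#' statistic.
#'
#' @param case_counts,control_counts Length-3 genotype counts
#'   (major homozygote, heterozygote, minor homozygote).
#' @return The trend statistic (0 for zero-variance input).
#' @export
trend_chi2 <- function(case_counts, control_counts) {
  if (length(case_counts) != 3L || length(control_counts) != 3L) {
    stop("genotype counts must have length 3")
  }
  if (sum(case_counts) < 1 || sum(control_counts) < 1) {
    stop("each group needs at least one genotyped sample")
  }
  trend_chi2_vec(matrix(case_counts, ncol = 1),
                 matrix(control_counts, ncol = 1))
}

# vectorized over SNPs: case_counts and control_counts are 3 x L
trend_chi2_vec <- function(case_counts, control_counts) {
  s <- c(0, 1, 2)
  r <- colSums(case_counts * s)        # sum s_i r_i
  n_tot <- case_counts + control_counts
  n_s <- colSums(n_tot * s)            # sum s_i n_i
  n_s2 <- colSums(n_tot * s^2)         # sum s_i^2 n_i
  R <- colSums(case_counts)
  N <- colSums(n_tot)
  num <- N * (N * r - R * n_s)^2
  den <- R * (N - R) * (N * n_s2 - n_s^2)
  chi2 <- rep(0, length(N))
  ok <- den > 0
  chi2[ok] <- num[ok] / den[ok]
  chi2
}

#' Per-SNP case-control association scan
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Named vector (sample id to 0 = control / 1 = case),
#'   logical or integer.
#' @param test `"trend"` (Cochran-Armitage, the default) or `"allelic"`
#'   (2x2 allele-count Pearson chi-squared, no continuity correction).
#' @return Numeric vector of per-SNP 1-df chi-squared statistics, named
#'   by SNP id. NoCall genotypes are excluded per SNP.
#' @export
assoc_scan <- function(gm, phenotypes, test = c("trend", "allelic")) {
  test <- match.arg(test)
  validate_genotype_matrix(gm)
  ids <- sample_ids(gm)
  missing <- setdiff(ids, names(phenotypes))
  if (length(missing) > 0L) {
    stop("samples without a phenotype: ", paste(missing, collapse = ", "))
  }
  ph <- as.integer(phenotypes[ids])
  if (any(!ph %in% c(0L, 1L))) stop("phenotypes must be 0 (control) or 1 (case)")
  if (sum(ph == 1L) == 0L || sum(ph == 0L) == 0L) {
    stop("association scan needs both cases and controls")
  }
  case_counts <- genotype_counts(gm$calls[ph == 1L, , drop = FALSE])
  ctrl_counts <- genotype_counts(gm$calls[ph == 0L, , drop = FALSE])
  chi2 <- if (test == "trend") {
    trend_chi2_vec(case_counts, ctrl_counts)
  } else {
    allelic_chi2_vec(case_counts, ctrl_counts)
  }
  stats::setNames(chi2, snp_ids(gm))
}

allelic_chi2_vec <- function(case_counts, control_counts) {
  a_case <- 2 * case_counts[1L, ] + case_counts[2L, ]   # major alleles
  b_case <- 2 * case_counts[3L, ] + case_counts[2L, ]
  a_ctrl <- 2 * control_counts[1L, ] + control_counts[2L, ]
  b_ctrl <- 2 * control_counts[3L, ] + control_counts[2L, ]
  n <- a_case + b_case + a_ctrl + b_ctrl
  num <- n * (a_case * b_ctrl - b_case * a_ctrl)^2
  den <- (a_case + b_case) * (a_ctrl + b_ctrl) * (a_case + a_ctrl) * (b_case + b_ctrl)
  chi2 <- rep(0, length(n))
  ok <- den > 0
  chi2[ok] <- num[ok] / den[ok]
  chi2
}

#' Genomic-control inflation factor
#'
#' The median of the per-SNP 1-df chi-squared association statistics,
#' divided by the theoretical median of the chi-squared(1) null
#' distribution (0.4549364). Lambda near 1 indicates no stratification;
#' lambda > 1 indicates stratification or other confounding.
#'
#' @param chi2_values Numeric vector of per-SNP statistics.
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(chi2_values) {
  if (length(chi2_values) == 0L) stop("no association statistics supplied")
  if (any(chi2_values < 0)) stop("chi-squared statistics must be non-negative")
  stats::median(chi2_values) / CHI2_1DF_NULL_MEDIAN
}

#' Does classifier-based sample exclusion reduce inflation?
#'
#' Computes the genomic-control lambda over all samples, then classifies
#' every sample with the trained ensemble, retains only samples whose
#' inclusion probability for `target_class` passes `cutoff` (see
#' [apply_inclusion_cutoff()]), and recomputes lambda on the retained
#' subset. On a cohort whose phenotype is confounded with population
#' membership, the retained (ancestrally homogeneous) subset should show
#' a smaller lambda.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Named 0/1 vector (control/case) per sample.
#' @param ensemble A trained `disjoint_ensemble`.
#' @param target_class Population under study.
#' @param cutoff Inclusion-probability cut-off in \[0, 1\].
#' @param test Association test passed to [assoc_scan()].
#' @return List with `lambda_before`, `lambda_after`, `n_before`,
#'   `n_after` and `kept` (sample ids).
#' @export
stratification_correction_experiment <- function(gm, phenotypes, ensemble,
                                                 target_class, cutoff,
                                                 test = "trend") {
  lambda_before <- genomic_lambda(assoc_scan(gm, phenotypes, test = test))
  preds <- predict_batch(ensemble, gm)
  kept <- apply_inclusion_cutoff(preds, target_class, cutoff)
  if (length(kept) == 0L) {
    stop("no samples pass the inclusion cut-off; cannot recompute lambda")
  }
  gm_kept <- subset_genotypes(gm, samples = kept)
  lambda_after <- genomic_lambda(assoc_scan(gm_kept, phenotypes, test = test))
  list(lambda_before = lambda_before, lambda_after = lambda_after,
       n_before = nrow(gm$calls), n_after = length(kept), kept = kept)
}
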