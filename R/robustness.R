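# Sizing the ensemble against missing genotypes. With per-SNP NoCall
# probability u (independent across SNPs) and an average of n SNPs per
# tree, a tree has all its SNPs called with probability p = (1 - u)^n.
# The number of clean trees among N is then Binomial(N, p), and the
# confidence of having at least m clean trees is the upper binomial
# tail. Choosing m so that size-m sub-ensembles already reach the target
# accuracy, the smallest N whose tail mass reaches the target confidence
# is the recommended ensemble size.

#' Probability that a tree has no missing SNP values
#'
#' @param n Average number of SNPs per tree (non-negative real).
#' @param u Per-SNP NoCall probability in \[0, 1\].
#' @return `(1 - u)^n`.
#' @export
coverage_prob <- function(n, u) {
  if (any(n < 0)) stop("n must be non-negative")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  (1 - u)^n
}

#' Average number of SNPs per tree of an ensemble
#'
#' @param ensemble A `disjoint_ensemble`.
#' @return Total SNPs used divided by the number of trees.
#' @export
avg_snps_per_tree <- function(ensemble) {
  stopifnot(inherits(ensemble, "disjoint_ensemble"))
  if (length(ensemble$trees) == 0L) stop("ensemble has no trees")
  sizes <- vapply(ensemble$trees, function(t) length(t$snp_set), integer(1))
  sum(sizes) / length(sizes)
}

#' Confidence of at least m clean trees among N
#'
#' The percent probability that at least `m` of `N` trees have no
#' missing SNP values when each tree independently has all its SNPs
#' called with probability `p`:
#' `100 * (1 - sum_{i=0}^{m-1} choose(N, i) p^i (1-p)^(N-i))`,
#' the upper tail of Binomial(N, p) at m.
#'
#' @param N Number of trees (>= 0).
#' @param m Required number of clean trees (>= 0; `m = 0` gives 100).
#' @param p Per-tree coverage probability in \[0, 1\].
#' @return Confidence in percent.
#' @export
ensemble_confidence <- function(N, m, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(N < 0) || any(m < 0)) stop("N and m must be non-negative")
  ifelse(m == 0, 100,
         100 * stats::pbinom(m - 1, size = N, prob = p, lower.tail = FALSE))
}

#' Smallest ensemble size reaching a target confidence
#'
#' Linear scan over N >= m for the first N whose
#' [ensemble_confidence()] reaches `conf_target`.
#'
#' @param m Required number of clean trees.
#' @param p Per-tree coverage probability, 0 < p <= 1.
#' @param conf_target Target confidence in percent, < 100.
#' @param n_max Scan cap (default 10000); exceeding it is an error.
#' @return The minimal integer N.
#' @export
min_trees_for_confidence <- function(m, p, conf_target, n_max = 10000L) {
  if (p <= 0 && conf_target > 0) {
    stop("p = 0: no ensemble size can reach a positive confidence")
  }
  if (conf_target >= 100) stop("conf_target must be < 100 percent")
  m <- as.integer(m)
  for (N in m:n_max) {
    if (ensemble_confidence(N, m, p) >= conf_target) return(N)
  }
  stop("no N <= ", n_max, " reaches ", conf_target, "% confidence")
}

# majority-vote accuracy (percent) of the trees in `rows` of an
# out-of-fold prediction matrix; an all-abstain (NO_CALL) vote counts
# as incorrect, ties break by class order
subset_vote_accuracy <- function(oof, rows, truth, class_order) {
  sub <- oof[rows, , drop = FALSE]
  correct <- vapply(seq_len(ncol(sub)), function(j) {
    v <- tally_votes(sub[, j], class_order)
    v$label != NO_CALL_LABEL && v$label == truth[j]
  }, logical(1))
  100 * mean(correct)
}

#' Minimal sub-ensemble size for a target accuracy
#'
#' For each candidate size s = 1..T, computes the average majority-vote
#' accuracy of size-s tree subsets on out-of-fold (cross-validated)
#' predictions — exhaustively when `choose(T, s) <= max_enumeration`,
#' otherwise over `n_samples_mc` seeded random subsets — and returns the
#' smallest s whose average reaches `acc_target`.
#'
#' @param oof_predictions Trees x samples character matrix of
#'   out-of-fold predicted labels (`NA` = the tree abstained), e.g.
#'   `cv$out_of_fold_predictions` from [kfold_cv()].
#' @param truth Character vector of true labels, one per column.
#' @param class_order Ordered class names (vote tie-break).
#' @param acc_target Target average accuracy in percent.
#' @param max_enumeration Exhaustive-enumeration cap (default 1e5).
#' @param n_samples_mc Monte-Carlo subset count above the cap (default 1e5).
#' @param seed Seed for the Monte-Carlo subsets.
#' @return List with `m` (minimal size, `NA` if unreachable),
#'   `reachable`, `best_size` (size with highest average accuracy) and
#'   `size_table` (data frame: size, n_subsets, exhaustive flag, mean
#'   accuracy).
#' @export
min_ensemble_size_for_accuracy <- function(oof_predictions, truth, class_order,
                                           acc_target,
                                           max_enumeration = 1e5,
                                           n_samples_mc = 1e5,
                                           seed = 1L) {
  T_n <- nrow(oof_predictions)
  if (is.null(T_n) || T_n < 1L) stop("need at least one tree of predictions")
  if (length(truth) != ncol(oof_predictions)) {
    stop("truth length must match the prediction columns")
  }
  if (acc_target > 100) stop("acc_target cannot exceed 100 percent")
  sizes <- seq_len(T_n)
  mean_acc <- numeric(T_n)
  n_subsets <- numeric(T_n)
  exhaustive <- logical(T_n)
  for (s in sizes) {
    n_comb <- choose(T_n, s)
    if (n_comb <= max_enumeration) {
      subsets <- utils::combn(T_n, s, simplify = FALSE)
      exhaustive[s] <- TRUE
    } else {
      subsets <- run_with_seed(seed + s, {
        lapply(seq_len(n_samples_mc), function(i) sample.int(T_n, s))
      })
    }
    n_subsets[s] <- length(subsets)
    accs <- vapply(subsets, subset_vote_accuracy, numeric(1),
                   oof = oof_predictions, truth = truth,
                   class_order = class_order)
    mean_acc[s] <- mean(accs)
  }
  ok <- which(mean_acc >= acc_target)
  list(
    m = if (length(ok) > 0L) min(ok) else NA_integer_,
    reachable = length(ok) > 0L,
    best_size = which.max(mean_acc),
    size_table = data.frame(size = sizes, n_subsets = n_subsets,
                            exhaustive = exhaustive, mean_accuracy = mean_acc)
  )
}

#' Build a robustness plan: how many trees does the ensemble need?
#'
#' Chains the sizing computations: average SNPs per tree (n), per-tree
#' coverage probability p = (1-u)^n, minimal accurate sub-ensemble size m
#' from cross-validated per-tree predictions, and the minimal N whose
#' binomial-tail confidence of >= m clean trees reaches `conf_target`.
#' Every intermediate symbol is recorded in the returned plan.
#'
#' @param ensemble A `disjoint_ensemble`.
#' @param cv_report A CV report from [kfold_cv()] (used for its
#'   out-of-fold predictions and truth); may be `NULL` when `m` is given.
#' @param u Assumed per-SNP NoCall probability.
#' @param acc_target Target average sub-ensemble accuracy in percent.
#' @param conf_target Target confidence in percent.
#' @param p Override for the coverage probability (default: computed as
#'   `(1-u)^n`). Useful for replaying a published sizing analysis whose
#'   p is quoted directly.
#' @param m Override for the minimal accurate sub-ensemble size.
#' @param ... Passed to [min_ensemble_size_for_accuracy()].
#' @return A list of class `robustness_plan` with fields `u`, `n`, `p`,
#'   `q`, `m`, `acc_target`, `conf_target`, `N` and `size_table`.
#' @export
build_plan <- function(ensemble, cv_report = NULL, u, acc_target,
                       conf_target, p = NULL, m = NULL, ...) {
  n <- avg_snps_per_tree(ensemble)
  if (is.null(p)) p <- coverage_prob(n, u)
  size_table <- NULL
  if (is.null(m)) {
    if (is.null(cv_report)) {
      stop("either a cv_report or an explicit m is required")
    }
    res <- min_ensemble_size_for_accuracy(
      cv_report$out_of_fold_predictions, cv_report$truth,
      cv_report$class_order, acc_target = acc_target, ...)
    if (!res$reachable) {
      stop("no sub-ensemble size reaches ", acc_target,
           "% accuracy (best: size ", res$best_size, ")")
    }
    m <- res$m
    size_table <- res$size_table
  }
  N <- min_trees_for_confidence(m, p, conf_target)
  structure(list(u = u, n = n, p = p, q = 1 - p, m = as.integer(m),
                 acc_target = acc_target, conf_target = conf_target,
                 N = N, size_table = size_table),
            class = "robustness_plan")
}

#' @export
print.robustness_plan <- function(x, ...) {
  cat("robustness_plan\n")
  cat(sprintf("  per-SNP NoCall probability u      %.4g\n", x$u))
  cat(sprintf("  average SNPs per tree n           %.4g\n", x$n))
  cat(sprintf("  per-tree coverage p = (1-u)^n     %.5f (q = %.5f)\n", x$p, x$q))
  cat(sprintf("  minimal accurate sub-ensemble m   %d (target %.4g%%)\n",
              x$m, x$acc_target))
  cat(sprintf("  recommended trees N               %d (confidence %.4g%% target %.4g%%)\n",
              x$N, ensemble_confidence(x$N, x$m, x$p), x$conf_target))
  invisible(x)
}

#' Confidence table over ensemble sizes
#'
#' @param m Required clean trees.
#' @param p Per-tree coverage probability.
#' @param N_max Largest size tabulated.
#' @return Data frame with `N` and `confidence` (percent) for N = 1..N_max.
#' @export
confidence_table <- function(m, p, N_max = 30L) {
  N <- seq_len(N_max)
  data.frame(N = N, confidence = ensemble_confidence(N, m, p))
}
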