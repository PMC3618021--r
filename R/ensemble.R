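# The disjoint-tree ensemble: trees are learned sequentially, each on
# the SNP pool minus every SNP used by earlier trees, so no SNP appears
# in two trees. A subject with missing genotypes therefore silences only
# the trees touching a missing SNP; the rest still vote.

new_disjoint_ensemble <- function(trees, class_order, snp_alleles, meta) {
  ens <- structure(list(trees = trees, class_order = class_order,
                        snp_alleles = snp_alleles, meta = meta),
                   class = "disjoint_ensemble")
  assert_disjoint(ens)
  ens
}

assert_disjoint <- function(ensemble) {
  sets <- lapply(ensemble$trees, `[[`, "snp_set")
  all_snps <- unlist(sets)
  if (anyDuplicated(all_snps)) {
    stop("ensemble trees share SNPs: ",
         paste(unique(all_snps[duplicated(all_snps)]), collapse = ", "))
  }
  missing <- setdiff(all_snps, names(ensemble$snp_alleles))
  if (length(missing) > 0L) {
    stop("tree SNPs lacking allele metadata: ", paste(missing, collapse = ", "))
  }
  invisible(ensemble)
}

#' SNPs used by an ensemble
#' @param ensemble A `disjoint_ensemble`.
#' @return Character vector: the union of the trees' SNP sets.
#' @export
ensemble_snps <- function(ensemble) {
  unique(unlist(lapply(ensemble$trees, `[[`, "snp_set")))
}

#' Train an ensemble of disjoint decision trees
#'
#' Learns `n_trees` trees in sequence. The first tree is fit on the full
#' SNP pool; its SNPs are then removed from the pool and the next tree is
#' fit on the remainder, and so on, so the trees' SNP sets are pairwise
#' disjoint by construction.
#'
#' @param gm A filtered [genotype_matrix()] (no NoCall entries).
#' @param labels A [population_labels()] with at least two classes.
#' @param n_trees Number of trees to learn. See [min_trees_for_confidence()]
#'   for how to size this against an expected per-SNP NoCall rate.
#' @param params A [tree_params()].
#' @return A `disjoint_ensemble`: `trees`, `class_order`, `snp_alleles`
#'   (SNP id to major/minor allele characters) and `meta`.
#' @export
train_ensemble <- function(gm, labels, n_trees, params = tree_params()) {
  validate_genotype_matrix(gm)
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (length(labels$class_order) < 2L) stop("training needs at least 2 classes")
  pool <- snp_ids(gm)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    if (length(pool) == 0L) {
      stop("SNP pool exhausted after ", i - 1L, " of ", n_trees,
           " trees; request fewer trees or supply more SNPs")
    }
    tree <- learn_tree(gm, labels, allowed_snps = pool, params = params)
    if (length(tree$snp_set) == 0L) {
      stop("no informative SNPs left after ", i - 1L, " of ", n_trees,
           " trees; request fewer trees or supply more SNPs")
    }
    trees[[i]] <- tree
    pool <- setdiff(pool, tree$snp_set)
  }
  used <- unlist(lapply(trees, `[[`, "snp_set"))
  info <- gm$snp_info[match(used, gm$snp_info$snp_id), , drop = FALSE]
  snp_alleles <- stats::setNames(
    lapply(seq_len(nrow(info)), function(i) {
      c(allele_major = info$allele_major[i], allele_minor = info$allele_minor[i])
    }),
    info$snp_id)
  new_disjoint_ensemble(
    trees = trees,
    class_order = labels$class_order,
    snp_alleles = snp_alleles,
    meta = list(params = params, n_trees_requested = n_trees,
                seed = params$seed)
  )
}

#' @export
print.disjoint_ensemble <- function(x, ...) {
  sizes <- vapply(x$trees, function(t) length(t$snp_set), integer(1))
  cat("disjoint_ensemble:", length(x$trees), "trees over", sum(sizes),
      "SNPs (", paste(x$class_order, collapse = ", "), ")\n")
  cat("  SNPs per tree:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# turn per-tree votes (character, NA = abstained) into a vote prediction
tally_votes <- function(tree_votes, class_order) {
  n_abstained <- sum(is.na(tree_votes))
  cast <- tree_votes[!is.na(tree_votes)]
  votes <- stats::setNames(integer(length(class_order)), class_order)
  if (length(cast) > 0L) {
    tab <- table(factor(cast, levels = class_order))
    votes[] <- as.integer(tab)
  }
  total <- sum(votes)
  if (total == 0L) {
    prob <- stats::setNames(rep(NA_real_, length(class_order)), class_order)
    label <- NO_CALL_LABEL
    tie <- FALSE
  } else {
    prob <- votes / total
    top <- max(votes)
    winners <- which(votes == top)
    label <- class_order[winners[1L]]   # smallest class_order index wins
    tie <- length(winners) > 1L
  }
  structure(list(votes = votes, n_abstained = n_abstained,
                 prob = prob, label = label, tie = tie),
            class = "vote_prediction")
}

#' @export
print.vote_prediction <- function(x, ...) {
  cat("vote_prediction: label =", x$label,
      if (x$tie) "(tie, broken by class order)" else "", "\n")
  cat("  votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "),
      "| abstained:", x$n_abstained, "\n")
  if (!all(is.na(x$prob))) {
    cat("  prob: ", paste(names(x$prob), sprintf("%.4f", x$prob),
                          sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict a subject's ancestry by abstention-aware majority vote
#'
#' Every tree whose SNPs are all called votes for one population; trees
#' touching a NoCall abstain. The returned probability vector divides
#' each class's votes by the number of *voting* trees (e.g. 15, 4 and 8
#' votes with 2 abstentions among 29 trees gives 15/27, 4/27, 8/27), and
#' the label is the class with the largest number of trees.
#'
#' @param object A `disjoint_ensemble`.
#' @param sample Named integer vector of genotype codes (0/1/2, `NA` for
#'   NoCall) covering every SNP the ensemble uses.
#' @param ... Unused.
#' @return A `vote_prediction`: `votes` (per class), `n_abstained`,
#'   `prob` (per class; `NA` when every tree abstained), `label` (class
#'   name, or `"NO_CALL"` when every tree abstained) and `tie`.
#' @export
predict.disjoint_ensemble <- function(object, sample, ...) {
  needed <- ensemble_snps(object)
  absent <- setdiff(needed, names(sample))
  if (length(absent) > 0L) {
    stop("sample lacks entries (not merely NoCall) for ensemble SNPs: ",
         paste(absent, collapse = ", "))
  }
  tree_votes <- vapply(object$trees, predict_tree, character(1), sample = sample)
  tally_votes(tree_votes, object$class_order)
}

#' Predict ancestry for every sample of a genotype matrix
#'
#' @param ensemble A `disjoint_ensemble`.
#' @param gm A [genotype_matrix()] containing every SNP the ensemble uses
#'   (additional SNPs are ignored).
#' @return List with `predictions` (one `vote_prediction` per sample) and
#'   `table` (a data frame: sample id, per-class vote counts, abstention
#'   count, per-class probabilities, label, tie flag).
#' @export
predict_batch <- function(ensemble, gm) {
  stopifnot(inherits(ensemble, "disjoint_ensemble"))
  validate_genotype_matrix(gm)
  needed <- ensemble_snps(ensemble)
  absent <- setdiff(needed, snp_ids(gm))
  if (length(absent) > 0L) {
    stop("matrix lacks ensemble SNPs: ", paste(absent, collapse = ", "))
  }
  calls <- gm$calls[, needed, drop = FALSE]
  ids <- sample_ids(gm)
  preds <- lapply(seq_along(ids), function(i) {
    predict(ensemble, row_named(calls, i))
  })
  names(preds) <- ids
  cls <- ensemble$class_order
  tab <- data.frame(
    sample_id = ids,
    stringsAsFactors = FALSE
  )
  for (cl in cls) {
    tab[[paste0("votes_", cl)]] <- vapply(preds, function(p) p$votes[[cl]], integer(1))
  }
  tab$abstained <- vapply(preds, function(p) p$n_abstained, integer(1))
  for (cl in cls) {
    tab[[paste0("prob_", cl)]] <- vapply(preds, function(p) p$prob[[cl]], numeric(1))
  }
  tab$label <- vapply(preds, function(p) p$label, character(1))
  tab$tie <- vapply(preds, function(p) p$tie, logical(1))
  rownames(tab) <- NULL
  list(predictions = preds, table = tab)
}

#' Keep samples whose inclusion probability for a class passes a cut-off
#'
#' A GWAS-facing convenience: retain subjects whose population-inclusion
#' probability for the population under study is at least `min_prob`
#' (subjects on which every tree abstained are always dropped).
#'
#' @param predictions A list of `vote_prediction`s (named by sample id),
#'   or the result of [predict_batch()].
#' @param target_class Class name of the population under study.
#' @param min_prob Probability cut-off in \[0, 1\].
#' @return Character vector of kept sample ids.
#' @export
apply_inclusion_cutoff <- function(predictions, target_class, min_prob) {
  if (is.list(predictions) && !is.null(predictions$predictions)) {
    predictions <- predictions$predictions
  }
  if (min_prob < 0 || min_prob > 1) stop("min_prob must lie in [0, 1]")
  if (length(predictions) == 0L) return(character(0))
  cls <- names(predictions[[1L]]$votes)
  if (!target_class %in% cls) {
    stop("unknown class '", target_class, "'; ensemble classes: ",
         paste(cls, collapse = ", "))
  }
  keep <- vapply(predictions, function(p) {
    p$label != NO_CALL_LABEL && !is.na(p$prob[[target_class]]) &&
      p$prob[[target_class]] >= min_prob
  }, logical(1))
  names(predictions)[keep]
}
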