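# CART over categorical genotype features. Each internal node tests one
# SNP against one of the three bipartitions of {A_A, A_B, B_B}:
#   {A_A} | {A_B, B_B}   (dominant pattern)
#   {A_B} | {A_A, B_B}   (heterozygote-specific)
#   {B_B} | {A_A, A_B}   (recessive pattern)
# listed in that fixed order for deterministic tie-breaking. The left
# branch holds the singleton genotype set.

leaf_node <- function(label, class_counts) {
  list(type = "leaf", label = label, class_counts = class_counts)
}

internal_node <- function(snp_id, left_genotypes, class_counts, left, right) {
  list(type = "internal", snp_id = snp_id,
       left_genotypes = left_genotypes, class_counts = class_counts,
       left = left, right = right)
}

collect_snp_set <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$snp_id,
           collect_snp_set(node$left),
           collect_snp_set(node$right)))
}

new_decision_tree <- function(root, class_order) {
  structure(list(root = root,
                 snp_set = collect_snp_set(root),
                 class_order = class_order),
            class = "decision_tree")
}

#' Training parameters for a single classification tree
#'
#' @param min_leaf_size Minimum training samples per leaf (default 5).
#' @param max_leaves Cap on leaf count, `Inf` for unbounded (default).
#' @param prune `"cost_complexity_1se"` (classical CART pruning: grow
#'   fully, compute the weakest-link alpha path, select the most-pruned
#'   subtree within one standard error of the internally cross-validated
#'   minimum) or `"none"`.
#' @param internal_cv_folds Folds for the internal pruning CV (default 10).
#' @param seed Integer seed controlling internal fold assignment.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(min_leaf_size = 5L, max_leaves = Inf,
                        prune = c("cost_complexity_1se", "none"),
                        internal_cv_folds = 10L, seed = 1L) {
  prune <- match.arg(prune)
  min_leaf_size <- as.integer(min_leaf_size)
  if (min_leaf_size < 1L) stop("min_leaf_size must be >= 1")
  if (prune == "cost_complexity_1se" && internal_cv_folds < 2L) {
    stop("internal_cv_folds must be >= 2 for cost-complexity pruning")
  }
  structure(list(min_leaf_size = min_leaf_size, max_leaves = max_leaves,
                 prune = prune,
                 internal_cv_folds = as.integer(internal_cv_folds),
                 seed = as.integer(seed)),
            class = "tree_params")
}

#' Gini impurity of a vector of class counts
#'
#' @param class_counts Non-negative per-class counts summing to >= 1.
#' @return `1 - sum((n_c / n)^2)`, in \[0, 1).
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  n <- sum(class_counts)
  if (n < 1) stop("class counts must sum to at least 1")
  1 - sum((class_counts / n)^2)
}

# Gini per column of a C x L count matrix (0 for empty columns)
gini_cols <- function(m) {
  n <- colSums(m)
  out <- rep(0, ncol(m))
  nz <- n > 0
  out[nz] <- 1 - colSums(m[, nz, drop = FALSE]^2) / n[nz]^2
  out
}

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# stratified fold assignment: within each class, a seeded shuffle then
# round-robin over folds, so per-fold class proportions stay within one
# sample of the global proportions
stratified_folds <- function(y, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (k > length(y)) stop("more folds than samples")
  fold <- integer(length(y))
  run_with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      # stagger the starting fold across classes to balance fold sizes
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# ---- growth -----------------------------------------------------------

grow_tree <- function(X, y, min_leaf_size, budget_env) {
  levels_y <- levels(y)
  n_class <- length(levels_y)

  recurse <- function(idx) {
    counts <- tabulate(as.integer(y[idx]), nbins = n_class)
    names(counts) <- levels_y
    label <- levels_y[which.max(counts)]
    make_leaf <- function() leaf_node(label = label, class_counts = counts)

    if (sum(counts > 0) <= 1L) return(make_leaf())           # pure
    if (length(idx) < 2L * min_leaf_size) return(make_leaf())
    if (budget_env$leaves_left <= 1L) return(make_leaf())

    Xs <- X[idx, , drop = FALSE]
    Ys <- matrix(0L, nrow = length(idx), ncol = n_class)
    Ys[cbind(seq_along(idx), as.integer(y[idx]))] <- 1L

    parent_gini <- 1 - sum((counts / length(idx))^2)
    n_node <- length(idx)

    dec_mat <- matrix(-Inf, nrow = 3L, ncol = ncol(Xs))
    for (g in 0:2) {
      left_ind <- Xs == g
      n_left <- colSums(left_ind)
      left_counts <- crossprod(Ys, left_ind)          # C x L
      right_counts <- counts - left_counts
      n_right <- n_node - n_left
      valid <- n_left >= min_leaf_size & n_right >= min_leaf_size
      if (!any(valid)) next
      wg <- (n_left * gini_cols(left_counts) +
             n_right * gini_cols(right_counts)) / n_node
      dec <- parent_gini - wg
      dec[!valid] <- -Inf
      dec_mat[g + 1L, ] <- dec
    }
    best_dec <- max(dec_mat)
    if (!is.finite(best_dec) || best_dec <= 1e-12) return(make_leaf())
    # tie-break: earliest SNP column, then bipartition in listing order
    cand <- which(dec_mat >= best_dec - 1e-10)
    cand_j <- (cand - 1L) %/% 3L + 1L
    cand_g <- (cand - 1L) %% 3L
    pick <- order(cand_j, cand_g)[1L]
    j <- cand_j[pick]
    g <- cand_g[pick]

    budget_env$leaves_left <- budget_env$leaves_left - 1L
    go_left <- X[idx, j] == g
    internal_node(
      snp_id = colnames(X)[j],
      left_genotypes = g,
      class_counts = counts,
      left = recurse(idx[go_left]),
      right = recurse(idx[!go_left])
    )
  }

  recurse(seq_along(y))
}

# ---- cost-complexity pruning ------------------------------------------

n_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

node_error <- function(node) sum(node$class_counts) - max(node$class_counts)

subtree_error <- function(node) {
  if (node$type == "leaf") return(node_error(node))
  subtree_error(node$left) + subtree_error(node$right)
}

# smallest weakest-link alpha over internal nodes (Inf for a leaf)
min_link_alpha <- function(node) {
  if (node$type == "leaf") return(Inf)
  g <- (node_error(node) - subtree_error(node)) / (n_leaves(node) - 1L)
  min(g, min_link_alpha(node$left), min_link_alpha(node$right))
}

# collapse, bottom-up, every internal node whose weakest-link alpha
# is <= alpha; yields the cost-complexity-optimal subtree T(alpha)
prune_at_alpha <- function(node, alpha, class_order) {
  if (node$type == "leaf") return(node)
  node$left <- prune_at_alpha(node$left, alpha, class_order)
  node$right <- prune_at_alpha(node$right, alpha, class_order)
  g <- (node_error(node) - subtree_error(node)) / (n_leaves(node) - 1L)
  if (g <= alpha + 1e-12) {
    counts <- node$class_counts
    leaf_node(label = class_order[which.max(counts)], class_counts = counts)
  } else {
    node
  }
}

# weakest-link alpha sequence of a grown tree (increasing, excludes 0)
alpha_sequence <- function(root, class_order) {
  alphas <- numeric(0)
  node <- root
  while (node$type != "leaf") {
    a <- max(min_link_alpha(node), 0)
    alphas <- c(alphas, a)
    node <- prune_at_alpha(node, a, class_order)
  }
  alphas
}

predict_node <- function(node, x_row) {
  while (node$type != "leaf") {
    node <- if (x_row[[node$snp_id]] %in% node$left_genotypes) node$left else node$right
  }
  node$label
}

row_named <- function(m, i) stats::setNames(m[i, ], colnames(m))

predict_rows <- function(root, X) {
  vapply(seq_len(nrow(X)), function(i) predict_node(root, row_named(X, i)),
         character(1))
}

prune_tree_cv <- function(root, X, y, params) {
  alphas <- alpha_sequence(root, levels(y))
  if (length(alphas) == 0L) return(root)
  # representative alpha per constant interval of the pruning path
  if (length(alphas) == 1L) {
    candidates <- c(0, alphas[1L])
  } else {
    candidates <- c(0, sqrt(alphas[-length(alphas)] * alphas[-1L]), alphas[length(alphas)])
  }
  candidates <- unique(candidates)

  k <- min(params$internal_cv_folds, length(y))
  if (k < 2L) return(root)
  fold <- stratified_folds(y, k, seed = params$seed)
  errors <- matrix(0, nrow = length(candidates), ncol = 1L)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 1L || sum(tr) < 2L * params$min_leaf_size) next
    env <- new.env()
    env$leaves_left <- if (is.finite(params$max_leaves)) as.integer(params$max_leaves) else .Machine$integer.max
    froot <- grow_tree(X[tr, , drop = FALSE], droplevels_keep(y[tr], levels(y)),
                       params$min_leaf_size, env)
    current <- froot
    for (ci in seq_along(candidates)) {
      current <- prune_at_alpha(current, candidates[ci], levels(y))
      pred <- predict_rows(current, X[!tr, , drop = FALSE])
      errors[ci, 1L] <- errors[ci, 1L] + sum(pred != as.character(y[!tr]))
    }
  }
  err_rate <- errors[, 1L] / length(y)
  i_min <- which.min(err_rate)
  se <- sqrt(err_rate[i_min] * (1 - err_rate[i_min]) / length(y))
  ok <- which(err_rate <= err_rate[i_min] + se)
  chosen <- candidates[max(ok)]   # most aggressive pruning within 1 SE
  prune_at_alpha(root, chosen, levels(y))
}

droplevels_keep <- function(y, lev) factor(as.character(y), levels = lev)

# ---- public operations ------------------------------------------------

#' Learn a single classification tree over genotype features
#'
#' Recursive binary partitioning: at each node, the (SNP, bipartition)
#' pair with the largest Gini impurity decrease over the three
#' bipartitions of \{A_A, A_B, B_B\} is chosen; growth stops at purity,
#' `min_leaf_size`, or when no informative split remains. Ties are broken
#' deterministically (earliest SNP in matrix column order, then the
#' bipartition listing order), so the learned tree is invariant to SNP
#' column permutations.
#'
#' @param gm A [genotype_matrix()] with no NoCall entries among
#'   `allowed_snps` (run [filter_snps()] first).
#' @param labels A [population_labels()] covering the samples.
#' @param allowed_snps SNP ids the tree may use (default: all).
#' @param params A [tree_params()].
#' @return A `decision_tree` (fields `root`, `snp_set`, `class_order`).
#' @export
learn_tree <- function(gm, labels, allowed_snps = NULL, params = tree_params()) {
  validate_genotype_matrix(gm)
  y <- label_factor(labels, gm)
  if (is.null(allowed_snps)) allowed_snps <- snp_ids(gm)
  if (length(allowed_snps) == 0L) stop("allowed_snps is empty")
  missing <- setdiff(allowed_snps, snp_ids(gm))
  if (length(missing) > 0L) {
    stop("allowed_snps not in matrix: ", paste(missing, collapse = ", "))
  }
  # keep matrix column order (the tie-break reference order)
  keep <- snp_ids(gm)[snp_ids(gm) %in% allowed_snps]
  X <- gm$calls[, keep, drop = FALSE]
  if (anyNA(X)) {
    stop("NoCall genotypes in training data; filter SNPs before learning")
  }
  # zero-variance SNPs carry no split information
  informative <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  n_class_present <- length(unique(as.character(y)))
  if (n_class_present < 2L) {
    warning("single-class training labels: returning a single-leaf tree")
  }
  if (!any(informative) || n_class_present < 2L) {
    counts <- table(y)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    root <- leaf_node(label = levels(y)[which.max(counts)], class_counts = counts)
    return(new_decision_tree(root, levels(y)))
  }
  X <- X[, informative, drop = FALSE]
  env <- new.env()
  env$leaves_left <- if (is.finite(params$max_leaves)) {
    as.integer(params$max_leaves)
  } else .Machine$integer.max
  root <- grow_tree(X, y, params$min_leaf_size, env)
  if (params$prune == "cost_complexity_1se" && root$type != "leaf") {
    root <- prune_tree_cv(root, X, y, params)
  }
  new_decision_tree(root, levels(y))
}

#' Predict with a single tree, abstaining on missing genotypes
#'
#' A tree votes only when *every* SNP it uses is called for the subject
#' (not merely the SNPs on the realized root-to-leaf path); otherwise it
#' abstains. Path-only abstention is available but off by default.
#'
#' @param tree A `decision_tree`.
#' @param sample Named integer vector of genotype codes (0/1/2, `NA` for
#'   NoCall) covering at least `tree$snp_set`.
#' @param require_all_snps If `TRUE` (default), abstain when any tree SNP
#'   is NoCall; if `FALSE`, abstain only when a NoCall is hit on the
#'   traversal path.
#' @return The predicted class name, or `NA_character_` for abstention.
#' @export
predict_tree <- function(tree, sample, require_all_snps = TRUE) {
  stopifnot(inherits(tree, "decision_tree"))
  absent <- setdiff(tree$snp_set, names(sample))
  if (length(absent) > 0L) {
    stop("sample lacks entries (not merely NoCall) for tree SNPs: ",
         paste(absent, collapse = ", "))
  }
  if (require_all_snps && anyNA(sample[tree$snp_set])) {
    return(NA_character_)
  }
  node <- tree$root
  while (node$type != "leaf") {
    g <- sample[[node$snp_id]]
    if (is.na(g)) return(NA_character_)
    node <- if (g %in% node$left_genotypes) node$left else node$right
  }
  node$label
}

#' Export a tree as a human-readable rule set
#'
#' One rule per leaf: the conjunction of genotype conditions on the
#' root-to-leaf path plus the leaf's population label.
#'
#' @param tree A `decision_tree`.
#' @return Character vector of `"IF ... THEN population = ..."` rules
#'   (a single-leaf tree yields one unconditional rule).
#' @export
tree_to_rules <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  geno_name <- function(codes) paste0("{", paste(GENO_TOKENS[codes + 1L], collapse = ", "), "}")
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      body <- if (length(conds) == 0L) "" else paste0("IF ", paste(conds, collapse = " AND "), " THEN ")
      return(paste0(body, "population = ", node$label))
    }
    left_set <- node$left_genotypes
    right_set <- setdiff(0:2, left_set)
    c(walk(node$left, c(conds, paste0(node$snp_id, " in ", geno_name(left_set)))),
      walk(node$right, c(conds, paste0(node$snp_id, " in ", geno_name(right_set)))))
  }
  walk(tree$root, character(0))
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("decision_tree:", length(x$snp_set), "SNP(s),",
      n_leaves(x$root), "leaf/leaves\n")
  cat(paste0("  ", tree_to_rules(x)), sep = "\n")
  invisible(x)
}
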