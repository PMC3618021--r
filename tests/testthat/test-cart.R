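test_that("gini impurity matches the direct formula", {
  expect_equal(gini_impurity(c(50, 50)), 0.5)
  expect_equal(gini_impurity(c(100, 0, 0)), 0)
  # brute-force 1 - sum(p^2) oracle
  cnt <- c(90, 45, 135)
  expect_equal(gini_impurity(cnt), 1 - sum((cnt / sum(cnt))^2))
  expect_equal(gini_impurity(c(90, 45, 135)), 22 / 36)
  expect_error(gini_impurity(c(0, 0)), "at least 1")
})

test_that("a perfectly separating SNP yields a one-split tree", {
  codes <- cbind(rep(1L, 20), c(rep(0L, 10), rep(2L, 10)))
  colnames(codes) <- c("noise", "sep")
  gm <- gm_from_codes(codes)
  labels <- population_labels(stats::setNames(rep(c("X", "Y"), each = 10),
                                              sample_ids(gm)))
  tree <- learn_tree(gm, labels)
  expect_equal(tree$snp_set, "sep")
  expect_equal(length(tree_to_rules(tree)), 2)
  preds <- apply(gm$calls, 1, function(s) predict_tree(tree, s))
  expect_equal(unname(preds), rep(c("X", "Y"), each = 10))
})

test_that("uninformative features give a single-leaf majority tree", {
  codes <- matrix(1L, nrow = 12, ncol = 4)
  gm <- gm_from_codes(codes)
  labels <- population_labels(
    stats::setNames(rep(c("X", "X", "Y"), each = 4), sample_ids(gm)))
  tree <- learn_tree(gm, labels)
  expect_equal(length(tree$snp_set), 0)
  expect_equal(tree$root$label, "X")
  expect_equal(tree_to_rules(tree), "population = X")
  # single-class labels degrade to a single leaf with a warning
  lab1 <- population_labels(stats::setNames(rep("X", 12), sample_ids(gm)),
                            class_order = c("X", "Y"))
  sep <- gm_from_codes(cbind(sep = c(rep(0L, 6), rep(2L, 6))))
  expect_warning(t1 <- learn_tree(sep, lab1), "single-class")
  expect_equal(length(t1$snp_set), 0)
})

test_that("greedy partitioning solves a two-SNP interaction exactly", {
  # class = parity of the two dominant-coded SNPs, four cells with
  # counts (3, 1, 2, 2) so the first greedy split is informative
  cells <- rbind(
    matrix(rep(c(0L, 0L), 3), ncol = 2, byrow = TRUE),   # X
    matrix(rep(c(0L, 2L), 1), ncol = 2, byrow = TRUE),   # Y
    matrix(rep(c(2L, 0L), 2), ncol = 2, byrow = TRUE),   # Y
    matrix(rep(c(2L, 2L), 2), ncol = 2, byrow = TRUE))   # X
  colnames(cells) <- c("s1", "s2")
  y <- c(rep("X", 3), rep("Y", 3), rep("X", 2))
  gm <- gm_from_codes(cells)
  labels <- population_labels(stats::setNames(y, sample_ids(gm)))
  tree <- learn_tree(gm, labels,
                     params = tree_params(min_leaf_size = 1, prune = "none"))
  n_internal <- function(node) {
    if (node$type == "leaf") return(0L)
    1L + n_internal(node$left) + n_internal(node$right)
  }
  expect_gte(n_internal(tree$root), 2)
  # exhaustive check over the four genotype cells
  for (i in seq_len(nrow(cells))) {
    expect_equal(predict_tree(tree, cells[i, ]), y[i])
  }
})

test_that("abstention triggers on any tree SNP, not only path SNPs", {
  # root tests s1; s2 only appears in the right subtree
  cls <- c("X", "Y")
  cnt <- function(x, y) stats::setNames(c(x, y), cls)
  root <- internal_node(
    snp_id = "s1", left_genotypes = 0L, class_counts = cnt(10, 10),
    left = leaf_node("X", cnt(10, 0)),
    right = internal_node(
      snp_id = "s2", left_genotypes = 2L, class_counts = cnt(0, 10),
      left = leaf_node("Y", cnt(0, 6)),
      right = leaf_node("X", cnt(0, 4))))
  tree <- new_decision_tree(root, cls)
  expect_setequal(tree$snp_set, c("s1", "s2"))

  # s1 = 0 would reach the left leaf without touching s2, but s2 is NoCall
  expect_equal(predict_tree(tree, c(s1 = 0L, s2 = NA)), NA_character_)
  # path-only mode is available but off by default
  expect_equal(predict_tree(tree, c(s1 = 0L, s2 = NA), require_all_snps = FALSE),
               "X")
  # an absent entry is a contract violation, distinct from NoCall
  expect_error(predict_tree(tree, c(s1 = 0L)), "s2")

  # exhaustive traversal oracle over all 3^2 complete genotype inputs
  for (g1 in 0:2) for (g2 in 0:2) {
    expected <- if (g1 == 0) "X" else if (g2 == 2) "Y" else "X"
    expect_equal(predict_tree(tree, c(s1 = g1, s2 = g2)), expected)
  }
  expect_equal(length(tree_to_rules(tree)), 3)
})

test_that("rule count equals leaf count on learned trees", {
  sim <- simulate_populations(3, 30, 120, fst = 0.2, seed = 13)
  tree <- learn_tree(sim$genotypes, sim$labels, params = tree_params(seed = 13))
  expect_equal(length(tree_to_rules(tree)), n_leaves(tree$root))
  expect_setequal(tree$snp_set, collect_snp_set(tree$root))
})

test_that("the learned tree is invariant to SNP column order", {
  sim <- simulate_populations(2, 40, 80, fst = 0.2, seed = 21)
  tree_a <- learn_tree(sim$genotypes, sim$labels, params = tree_params(seed = 1))
  perm <- rev(seq_len(80))
  gm_b <- subset_genotypes(sim$genotypes, snps = perm)
  tree_b <- learn_tree(gm_b, sim$labels, params = tree_params(seed = 1))
  expect_equal(sort(tree_to_rules(tree_a)), sort(tree_to_rules(tree_b)))
})

test_that("every split strictly decreases weighted Gini impurity", {
  sim <- simulate_populations(3, 40, 100, fst = 0.1, seed = 31)
  tree <- learn_tree(sim$genotypes, sim$labels,
                     params = tree_params(prune = "none"))
  check <- function(node) {
    if (node$type == "leaf") return(invisible(TRUE))
    n <- sum(node$class_counts)
    nl <- sum(node$left$class_counts)
    nr <- sum(node$right$class_counts)
    w <- (nl * gini_impurity(node$left$class_counts) +
          nr * gini_impurity(node$right$class_counts)) / n
    expect_lt(w, gini_impurity(node$class_counts))
    check(node$left); check(node$right)
  }
  check(tree$root)
})

test_that("an unpruned tree with min_leaf_size 1 reproduces consistent training labels", {
  sim <- simulate_populations(2, 25, 60, fst = 0.3, seed = 17)
  gm <- sim$genotypes
  y <- sim$labels$assignment[sample_ids(gm)]
  # only applicable when no two identical genotype rows carry different labels
  key <- apply(gm$calls, 1, paste, collapse = ",")
  consistent <- !any(tapply(y, key, function(v) length(unique(v))) > 1)
  expect_true(consistent)
  tree <- learn_tree(gm, sim$labels,
                     params = tree_params(min_leaf_size = 1, prune = "none"))
  preds <- apply(gm$calls, 1, function(s) predict_tree(tree, s))
  expect_equal(unname(preds), unname(y))
})

test_that("tree training accuracy agrees with an independent CART fit", {
  skip_if_not_installed("rpart")
  sim <- simulate_populations(3, 50, 60, fst = 0.2, seed = 23)
  gm <- sim$genotypes
  y <- factor(sim$labels$assignment[sample_ids(gm)])
  tree <- learn_tree(gm, sim$labels, params = tree_params(prune = "none"))
  ours <- mean(apply(gm$calls, 1, function(s) predict_tree(tree, s)) == y)

  df <- as.data.frame(lapply(as.data.frame(gm$calls), factor))
  df$y <- y
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(minbucket = 5, cp = 0,
                                                     xval = 0))
  theirs <- mean(predict(fit, df, type = "class") == y)
  expect_gte(ours, theirs - 0.02)
  expect_gte(ours, 0.9)
})
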