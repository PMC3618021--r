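# Fixture builders shared across test files. Everything is constructed
# in code; no binary fixtures.

# genotype matrix from a character matrix of tokens (A_A/A_B/B_B/NoCall)
gm_from_tokens <- function(tokens, chromosome = NULL, sample_ids = NULL,
                           snp_ids = NULL) {
  tokens <- as.matrix(tokens)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(tokens)
    if (is.null(snp_ids)) snp_ids <- paste0("rs", seq_len(ncol(tokens)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(tokens)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(tokens)))
  }
  if (is.null(chromosome)) chromosome <- rep("1", ncol(tokens))
  code <- match(tokens, c("A_A", "A_B", "B_B", "NoCall"))
  stopifnot(!anyNA(code))
  calls <- matrix(ifelse(code == 4L, NA_integer_, code - 1L),
                  nrow = nrow(tokens),
                  dimnames = list(sample_ids, snp_ids))
  info <- data.frame(snp_id = snp_ids,
                     chromosome = chromosome,
                     position = seq_len(ncol(tokens)) * 100L,
                     allele_major = "A", allele_minor = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, info)
}

# genotype matrix from an integer code matrix (0/1/2/NA)
gm_from_codes <- function(codes, chromosome = NULL) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes))) colnames(codes) <- paste0("rs", seq_len(ncol(codes)))
  if (is.null(rownames(codes))) rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  if (is.null(chromosome)) chromosome <- rep("1", ncol(codes))
  info <- data.frame(snp_id = colnames(codes),
                     chromosome = chromosome,
                     position = seq_len(ncol(codes)) * 100L,
                     allele_major = "A", allele_minor = "G",
                     stringsAsFactors = FALSE)
  storage.mode(codes) <- "integer"
  genotype_matrix(codes, info)
}

# a one-split tree: left branch (genotype in left_genotypes) -> left label
single_split_tree <- function(snp, left_genotypes, left_label, right_label,
                              class_order, n_left = 10, n_right = 10) {
  counts_of <- function(lab, n) {
    cnt <- stats::setNames(numeric(length(class_order)), class_order)
    cnt[lab] <- n
    cnt
  }
  root <- internal_node(
    snp_id = snp, left_genotypes = as.integer(left_genotypes),
    class_counts = counts_of(left_label, n_left) + counts_of(right_label, n_right),
    left = leaf_node(left_label, counts_of(left_label, n_left)),
    right = leaf_node(right_label, counts_of(right_label, n_right)))
  new_decision_tree(root, class_order)
}

leaf_only_tree <- function(label, class_order, n = 10) {
  cnt <- stats::setNames(numeric(length(class_order)), class_order)
  cnt[label] <- n
  new_decision_tree(leaf_node(label, cnt), class_order)
}

# assemble an ensemble directly from trees (for vote-math tests)
ensemble_from_trees <- function(trees, class_order) {
  used <- unique(unlist(lapply(trees, `[[`, "snp_set")))
  alleles <- stats::setNames(
    lapply(used, function(s) c(allele_major = "A", allele_minor = "G")),
    used)
  new_disjoint_ensemble(trees = trees, class_order = class_order,
                        snp_alleles = alleles,
                        meta = list(params = NULL, n_trees_requested = length(trees),
                                    seed = 0L))
}

# perfectly separable 3-population fixture: two disjoint groups of
# fully-informative SNPs (so two perfect disjoint trees exist), plus
# uninformative constant SNPs
separable_fixture <- function(per_class = 10) {
  classes <- c("P1", "P2", "P3")
  n <- per_class * 3L
  pattern <- rbind(
    P1 = c(0L, 0L),
    P2 = c(2L, 0L),
    P3 = c(2L, 2L)
  )
  codes <- matrix(0L, nrow = n, ncol = 6L)
  y <- rep(classes, each = per_class)
  for (i in seq_len(n)) {
    codes[i, 1:2] <- pattern[y[i], ]   # group 1 (snpA1, snpB1)
    codes[i, 3:4] <- pattern[y[i], ]   # group 2 (snpA2, snpB2)
  }
  codes[, 5:6] <- 1L                   # constant, uninformative
  colnames(codes) <- c("snpA1", "snpB1", "snpA2", "snpB2", "const1", "const2")
  gm <- gm_from_codes(codes)
  labels <- population_labels(stats::setNames(y, sample_ids(gm)),
                              class_order = classes)
  list(gm = gm, labels = labels)
}
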