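#' @keywords internal
"_PACKAGE"

# Genotype coding used throughout the package:
#   0L = homozygous for the major allele (token "A_A")
#   1L = heterozygous                    (token "A_B")
#   2L = homozygous for the minor allele (token "B_B")
#   NA = failed call                     (token "NoCall")
# "Major"/"minor" are labels for a stored allele pair, not dataset-relative
# codes: a trained model carries each SNP's (allele_major, allele_minor)
# characters so genotypes can be matched across datasets as unordered
# allele pairs.

GENO_TOKENS <- c("A_A", "A_B", "B_B", "NoCall")
NO_CALL_LABEL <- "NO_CALL"

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT", "UNKNOWN")
AUTOSOMES <- as.character(1:22)

#' Construct a genotype matrix
#'
#' The central container: an integer matrix of genotype calls
#' (samples in rows, SNPs in columns; values 0 = major homozygote,
#' 1 = heterozygote, 2 = minor homozygote, `NA` = NoCall) plus per-SNP
#' metadata.
#'
#' @param calls Integer matrix, samples x SNPs, entries in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names SNP ids (supplied here or via
#'   dimnames).
#' @param snp_info Data frame with columns `snp_id`, `chromosome`,
#'   `position`, `allele_major`, `allele_minor`; one row per SNP, in
#'   column order of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_info) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
  required <- c("snp_id", "chromosome", "position", "allele_major", "allele_minor")
  missing_cols <- setdiff(required, names(snp_info))
  if (length(missing_cols) > 0L) {
    stop("snp_info lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  snp_info$snp_id <- as.character(snp_info$snp_id)
  snp_info$chromosome <- as.character(snp_info$chromosome)
  snp_info$position <- as.integer(snp_info$position)
  if (nrow(snp_info) != ncol(calls)) {
    stop("snp_info has ", nrow(snp_info), " rows but calls has ",
         ncol(calls), " columns")
  }
  if (is.null(colnames(calls))) colnames(calls) <- snp_info$snp_id
  if (is.null(rownames(calls))) {
    rownames(calls) <- if (nrow(calls) > 0L) paste0("S", seq_len(nrow(calls))) else character(0)
  }
  rownames(snp_info) <- NULL
  gm <- structure(list(calls = calls, snp_info = snp_info),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  info <- gm$snp_info
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(info$snp_id)) stop("duplicate SNP ids")
  if (ncol(calls) > 0L && !identical(colnames(calls), info$snp_id)) {
    stop("calls column names do not match snp_info$snp_id")
  }
  if (any(!info$chromosome %in% VALID_CHROMOSOMES)) {
    stop("chromosome must be one of 1..22, X, Y, MT, UNKNOWN")
  }
  if (nrow(info) > 0L && any(info$position < 1L, na.rm = TRUE)) {
    stop("positions are 1-based and must be >= 1")
  }
  same <- info$allele_major == info$allele_minor
  if (any(same)) stop("allele_major and allele_minor must differ")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  ncall <- sum(is.na(x$calls))
  cat("  NoCall entries:", ncall,
      sprintf("(%.2f%%)\n", 100 * ncall / max(1L, length(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Sample ids of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' SNP ids of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of SNP ids.
#' @export
snp_ids <- function(gm) gm$snp_info$snp_id

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm A `genotype_matrix`.
#' @param samples Sample ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return A `genotype_matrix` restricted to the selection, order preserved
#'   as given.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  calls <- gm$calls
  info <- gm$snp_info
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(calls))
      if (length(missing) > 0L) {
        stop("unknown sample ids: ", paste(missing, collapse = ", "))
      }
    }
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      missing <- setdiff(snps, info$snp_id)
      if (length(missing) > 0L) {
        stop("unknown SNP ids: ", paste(missing, collapse = ", "))
      }
      snps <- match(snps, info$snp_id)
    }
    calls <- calls[, snps, drop = FALSE]
    info <- info[snps, , drop = FALSE]
  }
  genotype_matrix(calls, info)
}

#' Construct population labels
#'
#' @param assignment Named character vector mapping sample id to class
#'   (population) name, or an unnamed vector paired with `sample_ids`.
#' @param class_order Ordered unique class names; defaults to order of
#'   first appearance in `assignment`. Class order is the deterministic
#'   tie-break used by leaves and by majority voting.
#' @param sample_ids Sample ids when `assignment` is unnamed.
#' @return An object of class `population_labels` with fields
#'   `assignment` (named character) and `class_order`.
#' @export
population_labels <- function(assignment, class_order = NULL, sample_ids = NULL) {
  assignment <- stats::setNames(as.character(assignment),
                                if (!is.null(sample_ids)) sample_ids else names(assignment))
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("every assignment needs a sample id")
  }
  if (anyDuplicated(names(assignment))) stop("duplicate sample ids in labels")
  if (is.null(class_order)) class_order <- unique(assignment)
  class_order <- as.character(class_order)
  if (anyDuplicated(class_order)) stop("class_order must be unique")
  unknown <- setdiff(unique(assignment), class_order)
  if (length(unknown) > 0L) {
    stop("assigned classes missing from class_order: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(assignment = assignment, class_order = class_order),
            class = "population_labels")
}

#' @export
print.population_labels <- function(x, ...) {
  cat("population_labels:", length(x$assignment), "samples,",
      length(x$class_order), "classes\n")
  print(table(factor(x$assignment, levels = x$class_order)))
  invisible(x)
}

# labels aligned to a genotype matrix's samples, as a factor
label_factor <- function(labels, gm) {
  ids <- sample_ids(gm)
  missing <- setdiff(ids, names(labels$assignment))
  if (length(missing) > 0L) {
    stop("samples without a population label: ", paste(missing, collapse = ", "))
  }
  factor(labels$assignment[ids], levels = labels$class_order)
}
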