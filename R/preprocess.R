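# SNP exclusion criteria applied before tree learning:
#   (a) any NoCall among the samples (call rate < 100%),
#   (b) non-autosomal location (X, Y, MT or unknown chromosome),
#   (c) genotype frequencies deviating from Hardy-Weinberg equilibrium
#       (Pearson chi-squared, 1 df, nominal p < alpha).

#' Filter configuration for SNP quality control
#'
#' @param require_full_call_rate Flag SNPs with any NoCall (default TRUE).
#' @param autosomes_only Flag SNPs on X, Y, MT or unknown chromosomes
#'   (default TRUE).
#' @param hwe_alpha Nominal significance level for the Hardy-Weinberg
#'   test (default 0.05); set to `NA` to disable the HWE criterion.
#' @param hwe_scope `"per_population_union"` (test within each labelled
#'   population and flag a SNP deviating in any of them; the default) or
#'   `"pooled"` (test on all samples together). Pooled testing on a
#'   stratified cohort flags exactly the ancestry-informative SNPs the
#'   classifier needs (the Wahlund effect), so per-population testing is
#'   the default.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(require_full_call_rate = TRUE,
                          autosomes_only = TRUE,
                          hwe_alpha = 0.05,
                          hwe_scope = c("per_population_union", "pooled")) {
  hwe_scope <- match.arg(hwe_scope)
  if (!is.na(hwe_alpha) && (hwe_alpha <= 0 || hwe_alpha >= 1)) {
    stop("hwe_alpha must lie strictly between 0 and 1")
  }
  structure(list(require_full_call_rate = isTRUE(require_full_call_rate),
                 autosomes_only = isTRUE(autosomes_only),
                 hwe_alpha = hwe_alpha,
                 hwe_scope = hwe_scope),
            class = "filter_config")
}

#' Per-SNP call rate
#'
#' @param gm A [genotype_matrix()].
#' @param snp_id One or more SNP ids.
#' @return Fraction of samples with a non-NoCall genotype, in \[0, 1\].
#' @export
call_rate <- function(gm, snp_id) {
  idx <- match(snp_id, snp_ids(gm))
  if (anyNA(idx)) {
    stop("unknown SNP id: ", paste(snp_id[is.na(idx)], collapse = ", "))
  }
  n <- nrow(gm$calls)
  if (n == 0L) stop("genotype matrix has no samples")
  colSums(!is.na(gm$calls[, idx, drop = FALSE])) / n
}

#' Pearson chi-squared test for Hardy-Weinberg equilibrium
#'
#' Tests observed genotype counts against the proportions
#' (p^2, 2pq, q^2) expected at the sample allele frequency; 1 degree of
#' freedom, no continuity correction. A monomorphic SNP is returned as
#' chi2 = 0, p = 1.
#'
#' @param n_AA,n_AB,n_BB Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return List with `chi2` and `p`.
#' @export
hwe_chi2 <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (sum(counts) < 1) stop("need at least one genotyped sample")
  chi2 <- hwe_chi2_vec(n_AA, n_AB, n_BB)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# vectorized over SNPs; returns the statistic only
hwe_chi2_vec <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  p_hat <- ifelse(n > 0, (2 * n_AA + n_AB) / (2 * n), NA_real_)
  e_AA <- n * p_hat^2
  e_AB <- 2 * n * p_hat * (1 - p_hat)
  e_BB <- n * (1 - p_hat)^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(n_AA, e_AA) + term(n_AB, e_AB) + term(n_BB, e_BB)
  # monomorphic: expected heterozygote/minor counts are 0 and observed 0
  chi2[n > 0 & (p_hat == 0 | p_hat == 1)] <- 0
  chi2[n == 0] <- 0
  chi2
}

genotype_counts <- function(calls) {
  # calls: integer matrix; returns 3 x L matrix of per-SNP genotype counts
  rbind(n_AA = colSums(calls == 0L, na.rm = TRUE),
        n_AB = colSums(calls == 1L, na.rm = TRUE),
        n_BB = colSums(calls == 2L, na.rm = TRUE))
}

#' Apply the SNP exclusion criteria
#'
#' Flags each SNP independently under every enabled criterion and removes
#' the union of flagged sets; the report counts each criterion separately
#' (a SNP may be flagged by several) plus the union.
#'
#' @param gm A [genotype_matrix()].
#' @param labels A [population_labels()]; required when
#'   `config$hwe_scope == "per_population_union"`, ignored for pooled HWE.
#' @param config A [filter_config()].
#' @return List with `matrix` (the filtered [genotype_matrix()]) and
#'   `report` (class `filter_report`: `n_total`, `n_callrate_flagged`,
#'   `n_nonautosomal_flagged`, `n_hwe_flagged`, `n_filtered`,
#'   `n_unfiltered`, plus the flagged id sets).
#' @export
filter_snps <- function(gm, labels = NULL, config = filter_config()) {
  validate_genotype_matrix(gm)
  stopifnot(inherits(config, "filter_config"))
  calls <- gm$calls
  ids <- snp_ids(gm)
  flag_callrate <- flag_chrom <- flag_hwe <- rep(FALSE, length(ids))

  if (config$require_full_call_rate) {
    flag_callrate <- colSums(is.na(calls)) > 0L
  }
  if (config$autosomes_only) {
    flag_chrom <- !gm$snp_info$chromosome %in% AUTOSOMES
  }
  hwe_on <- !is.na(config$hwe_alpha)
  if (hwe_on) {
    if (config$hwe_scope == "per_population_union") {
      if (is.null(labels)) {
        stop("per-population HWE testing requires population labels")
      }
      y <- label_factor(labels, gm)
      for (cl in levels(y)) {
        sub <- calls[y == cl, , drop = FALSE]
        if (nrow(sub) == 0L) next
        cnt <- genotype_counts(sub)
        chi2 <- hwe_chi2_vec(cnt[1L, ], cnt[2L, ], cnt[3L, ])
        p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
        flag_hwe <- flag_hwe | (colSums(cnt) > 0L & p < config$hwe_alpha)
      }
    } else {
      cnt <- genotype_counts(calls)
      chi2 <- hwe_chi2_vec(cnt[1L, ], cnt[2L, ], cnt[3L, ])
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      flag_hwe <- colSums(cnt) > 0L & p < config$hwe_alpha
    }
  }

  flagged <- flag_callrate | flag_chrom | flag_hwe
  report <- structure(list(
    n_total = length(ids),
    n_callrate_flagged = sum(flag_callrate),
    n_nonautosomal_flagged = sum(flag_chrom),
    n_hwe_flagged = sum(flag_hwe),
    n_filtered = sum(flagged),
    n_unfiltered = sum(!flagged),
    callrate_flagged = ids[flag_callrate],
    nonautosomal_flagged = ids[flag_chrom],
    hwe_flagged = ids[flag_hwe]
  ), class = "filter_report")
  list(matrix = subset_genotypes(gm, snps = which(!flagged)),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report\n")
  cat(sprintf("  Total SNPs                         %d\n", x$n_total))
  cat(sprintf("  SNPs with call rate < 100%%         %d\n", x$n_callrate_flagged))
  cat(sprintf("  SNPs on X/Y/MT/unknown chromosome  %d\n", x$n_nonautosomal_flagged))
  cat(sprintf("  SNPs deviating from HWE            %d\n", x$n_hwe_flagged))
  cat(sprintf("  Filtered SNPs (union)              %d\n", x$n_filtered))
  cat(sprintf("  Unfiltered SNPs                    %d\n", x$n_unfiltered))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `filter_report` from [filter_snps()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    statistic = c("Total SNPs", "SNPs with Call Rate < 100%",
                  "SNPs on X/Y/MT/unknown chromosome",
                  "SNPs deviating from HWE", "Filtered SNPs",
                  "Unfiltered SNPs"),
    count = c(report$n_total, report$n_callrate_flagged,
              report$n_nonautosomal_flagged, report$n_hwe_flagged,
              report$n_filtered, report$n_unfiltered)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
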