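# Balding-Nichols genotype simulator. Each SNP draws an ancestral
# allele frequency pi ~ Uniform(lo, hi); population k then draws its own
# frequency from Beta(pi (1-F)/F, (1-pi) (1-F)/F), whose mean is pi and
# whose spread around pi grows with the divergence parameter F (F_ST).
# Genotypes are Binomial(2, freq) minor-allele counts, independently
# masked to NoCall with probability u. This emulates the systematic
# allele-frequency differences between subpopulations that drive both
# ancestry prediction and stratification confounding; it has no linkage
# disequilibrium, admixture or genotyping-batch structure.

#' Simulate genotypes for K diverged populations
#'
#' @param n_populations Number of populations K (>= 1).
#' @param samples_per_population Integer count, or a length-K vector.
#' @param n_snps Number of SNPs L.
#' @param fst Balding-Nichols divergence F in \[0, 1); `0` gives
#'   undifferentiated populations.
#' @param ancestral_freq_range Range (lo, hi) of the ancestral allele
#'   frequency, default `c(0.1, 0.9)`.
#' @param nocall_rate Per-call NoCall probability u in \[0, 1).
#' @param n_nonautosomal Extra SNPs placed on X/Y/MT (cycled), to
#'   exercise the chromosome filter (default 0).
#' @param seed Integer seed; the run is fully reproducible.
#' @param pop_names Population names (default POP1..POPK).
#' @return List with `genotypes` (a [genotype_matrix()]), `labels`
#'   (a [population_labels()]) and `truth` (K x L matrix of the true
#'   per-population minor-allele frequencies).
#' @export
simulate_populations <- function(n_populations,
                                 samples_per_population,
                                 n_snps,
                                 fst = 0.15,
                                 ancestral_freq_range = c(0.1, 0.9),
                                 nocall_rate = 0,
                                 n_nonautosomal = 0L,
                                 seed = 1L,
                                 pop_names = NULL) {
  K <- as.integer(n_populations)
  if (K < 1L) stop("need at least one population")
  sizes <- rep_len(as.integer(samples_per_population), K)
  if (any(sizes < 1L)) stop("samples_per_population must be >= 1")
  L <- as.integer(n_snps)
  if (L < 1L) stop("need at least one SNP")
  lo <- ancestral_freq_range[1L]; hi <- ancestral_freq_range[2L]
  if (!(lo > 0 && hi < 1 && lo < hi)) {
    stop("ancestral_freq_range must satisfy 0 < lo < hi < 1")
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (nocall_rate < 0 || nocall_rate >= 1) stop("nocall_rate must lie in [0, 1)")
  if (is.null(pop_names)) pop_names <- paste0("POP", seq_len(K))
  n_extra <- as.integer(n_nonautosomal)
  L_total <- L + n_extra

  run_with_seed(seed, {
    pi0 <- stats::runif(L_total, lo, hi)
    truth <- matrix(NA_real_, nrow = K, ncol = L_total,
                    dimnames = list(pop_names, NULL))
    for (k in seq_len(K)) {
      truth[k, ] <- if (fst == 0) {
        pi0
      } else {
        stats::rbeta(L_total,
                     shape1 = pi0 * (1 - fst) / fst,
                     shape2 = (1 - pi0) * (1 - fst) / fst)
      }
    }
    n_total <- sum(sizes)
    pop_of <- rep(seq_len(K), times = sizes)
    calls <- matrix(NA_integer_, nrow = n_total, ncol = L_total)
    for (k in seq_len(K)) {
      rows <- which(pop_of == k)
      calls[rows, ] <- stats::rbinom(length(rows) * L_total, size = 2L,
                                     prob = rep(truth[k, ], each = length(rows)))
    }
    if (nocall_rate > 0) {
      mask <- stats::runif(length(calls)) < nocall_rate
      calls[mask] <- NA_integer_
    }
    snp_id <- paste0("snp", seq_len(L_total))
    chrom <- c(AUTOSOMES[((seq_len(L) - 1L) %% 22L) + 1L],
               rep_len(c("X", "Y", "MT"), n_extra))
    info <- data.frame(
      snp_id = snp_id,
      chromosome = chrom,
      position = 1000L + 10L * seq_len(L_total),
      allele_major = "A",
      allele_minor = "B",
      stringsAsFactors = FALSE
    )
    rownames(calls) <- paste0("S", seq_len(n_total))
    colnames(calls) <- snp_id
    colnames(truth) <- snp_id
    gm <- genotype_matrix(calls, info)
    labels <- population_labels(
      stats::setNames(pop_names[pop_of], rownames(calls)),
      class_order = pop_names)
    list(genotypes = gm, labels = labels, truth = truth)
  })
}

#' Simulate a case-control cohort with population-confounded phenotype
#'
#' Genotypes are drawn exactly as in [simulate_populations()]; every
#' sample is then assigned case status with its population's case
#' fraction. No SNP has a true phenotype effect, so any association
#' signal downstream is pure population stratification.
#'
#' @inheritParams simulate_populations
#' @param case_fraction_per_population Length-K vector of case
#'   probabilities in \[0, 1\]. Unequal fractions confound phenotype with
#'   ancestry (inflating the genomic-control lambda); equal fractions
#'   give a null cohort.
#' @return List with `genotypes`, `labels`, `truth` and `phenotypes`
#'   (named 0/1 integer vector).
#' @export
simulate_case_control <- function(n_populations,
                                  samples_per_population,
                                  n_snps,
                                  case_fraction_per_population,
                                  fst = 0.15,
                                  ancestral_freq_range = c(0.1, 0.9),
                                  nocall_rate = 0,
                                  seed = 1L,
                                  pop_names = NULL) {
  K <- as.integer(n_populations)
  frac <- rep_len(case_fraction_per_population, K)
  if (any(frac < 0 | frac > 1)) stop("case fractions must lie in [0, 1]")
  sim <- simulate_populations(
    n_populations = K,
    samples_per_population = samples_per_population,
    n_snps = n_snps, fst = fst,
    ancestral_freq_range = ancestral_freq_range,
    nocall_rate = nocall_rate, seed = seed, pop_names = pop_names)
  assignment <- sim$labels$assignment
  pop_index <- match(assignment, sim$labels$class_order)
  phen <- run_with_seed(seed + 1L, {
    as.integer(stats::runif(length(pop_index)) < frac[pop_index])
  })
  names(phen) <- names(assignment)
  c(sim, list(phenotypes = phen))
}
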