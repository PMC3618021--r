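test_that("cross-validation is deterministic and partitions are stratified", {
  sim <- simulate_populations(3, 12, 120, fst = 0.25, seed = 14)
  cv1 <- kfold_cv(sim$genotypes, sim$labels, k = 4, n_trees = 2,
                  params = tree_params(seed = 14), seed = 14)
  cv2 <- kfold_cv(sim$genotypes, sim$labels, k = 4, n_trees = 2,
                  params = tree_params(seed = 14), seed = 14)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$out_of_fold_predictions, cv2$out_of_fold_predictions)
  expect_identical(cv1$per_tree_acc, cv2$per_tree_acc)

  # folds partition the samples and stay within one sample of the
  # global class proportions
  fold <- cv1$fold_assignment
  expect_setequal(names(fold), sample_ids(sim$genotypes))
  y <- sim$labels$assignment[names(fold)]
  for (cl in sim$labels$class_order) {
    per_fold <- table(factor(fold[y == cl], levels = 1:4))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  # cumulative accuracy at size 1 is the first tree's accuracy
  expect_equal(cv1$cumulative_acc$mean[1], cv1$per_tree_acc$mean[1])
  expect_true(all(cv1$per_tree_acc$sd >= 0))
})

test_that("perfectly separable data cross-validates at 100% for every size", {
  fix <- separable_fixture(per_class = 15)
  cv <- kfold_cv(fix$gm, fix$labels, k = 5, n_trees = 2,
                 params = tree_params(min_leaf_size = 1), seed = 1)
  expect_equal(cv$cumulative_acc$mean, c(100, 100))
  expect_equal(cv$cumulative_acc$sd, c(0, 0))
})

test_that("leave-one-out produces n singleton folds", {
  sim <- simulate_populations(2, 5, 40, fst = 0.3, seed = 16)
  expect_warning(
    cv <- kfold_cv(sim$genotypes, sim$labels, k = 10, n_trees = 1,
                   params = tree_params(min_leaf_size = 1), seed = 16),
    "fewer than k")
  expect_equal(sort(as.integer(table(cv$fold_assignment))), rep(1L, 10))
})

test_that("percent agreement is the diagonal share of the confusion table", {
  # self-declared vs predicted lineage tables for a 348-subject cohort
  t5 <- matrix(c(330, 11, 0, 7), nrow = 2)
  expect_equal(round(percent_agreement(t5), 1), 96.8)
  expect_equal(percent_agreement(t5), 100 * 337 / 348)
  t6 <- matrix(c(321, 9, 0, 18), nrow = 2)
  expect_equal(round(percent_agreement(t6), 1), 97.4)
  expect_equal(percent_agreement(t6), 100 * 339 / 348)
  expect_equal(percent_agreement(diag(c(5, 8, 2))), 100)
  expect_error(percent_agreement(matrix(0, 2, 2)), "empty")
})

test_that("trend chi-squared matches hand evaluation and scales like a trend statistic", {
  # identical distributions: no trend
  expect_equal(trend_chi2(c(10, 20, 10), c(10, 20, 10)), 0)
  # hand-evaluated textbook formula (frozen before implementation):
  # cases (10,10,0), controls (0,10,10): N=40, R=20, sum s*r=10,
  # sum s*n=40, sum s^2*n=60 ->
  # 40*(40*10-20*40)^2 / (20*20*(40*60-1600)) = 6.4e6/3.2e5 = 20
  expect_equal(trend_chi2(c(10, 10, 0), c(0, 10, 10)), 20)
  # doubling all counts doubles the statistic
  expect_equal(trend_chi2(c(20, 20, 0), c(0, 20, 20)), 40)
  # zero genotype variance: statistic 0
  expect_equal(trend_chi2(c(15, 0, 0), c(12, 0, 0)), 0)

  # cross-check against the base-R trend test on random tables
  set.seed(77)
  for (i in 1:20) {
    cases <- as.numeric(rmultinom(1, 60, c(0.4, 0.4, 0.2)))
    ctrls <- as.numeric(rmultinom(1, 80, c(0.3, 0.5, 0.2)))
    ref <- suppressWarnings(
      stats::prop.trend.test(cases, cases + ctrls, score = 0:2))
    expect_equal(trend_chi2(cases, ctrls), unname(ref$statistic))
  }
})

test_that("association scan matches per-SNP trend tests and excludes NoCalls", {
  sim <- simulate_case_control(2, 25, 30, case_fraction_per_population = c(0.7, 0.3),
                               fst = 0.2, nocall_rate = 0.1, seed = 18)
  chi2 <- assoc_scan(sim$genotypes, sim$phenotypes)
  expect_length(chi2, 30)
  ph <- sim$phenotypes[sample_ids(sim$genotypes)]
  for (j in c(1, 15, 30)) {
    col <- sim$genotypes$calls[, j]
    keep <- !is.na(col)
    cases <- tabulate(col[keep & ph == 1] + 1L, 3)
    ctrls <- tabulate(col[keep & ph == 0] + 1L, 3)
    expect_equal(unname(chi2[j]), trend_chi2(cases, ctrls))
  }
  # the allelic 2x2 option agrees with chisq.test without correction
  chi2_allelic <- assoc_scan(sim$genotypes, sim$phenotypes, test = "allelic")
  j <- 3
  col <- sim$genotypes$calls[, j]; keep <- !is.na(col)
  tab <- rbind(c(sum(2 * (col[keep & ph == 1] == 0)) + sum(col[keep & ph == 1] == 1),
                 sum(2 * (col[keep & ph == 1] == 2)) + sum(col[keep & ph == 1] == 1)),
               c(sum(2 * (col[keep & ph == 0] == 0)) + sum(col[keep & ph == 0] == 1),
                 sum(2 * (col[keep & ph == 0] == 2)) + sum(col[keep & ph == 0] == 1)))
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(unname(chi2_allelic[j]), unname(ref$statistic))
})

test_that("genomic lambda is median over the chi-squared(1) null median", {
  expect_equal(genomic_lambda(rep(0.4549364, 5)), 1)
  x <- c(0.1, 0.3, 0.8, 1.2, 5)
  expect_equal(genomic_lambda(2 * x), 2 * genomic_lambda(x))
  # chi-squared(1) draws concentrate lambda at 1
  set.seed(123)
  expect_lt(abs(genomic_lambda(rchisq(1e5, df = 1)) - 1), 0.05)
  expect_error(genomic_lambda(numeric(0)), "no association")
})

test_that("a null cohort shows no inflation", {
  # no stratification: one panmictic population, phenotype independent
  # of genotype, 10^4 SNPs
  sim <- simulate_case_control(1, 200, 1e4, case_fraction_per_population = 0.5,
                               fst = 0, seed = 20)
  lam <- genomic_lambda(assoc_scan(sim$genotypes, sim$phenotypes))
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("classifier-based exclusion reduces stratification inflation", {
  sim <- simulate_case_control(2, 120, 800,
                               case_fraction_per_population = c(0.8, 0.2),
                               fst = 0.1, seed = 22)
  ens <- train_ensemble(sim$genotypes, sim$labels, n_trees = 3,
                        params = tree_params(seed = 22))
  res <- stratification_correction_experiment(
    sim$genotypes, sim$phenotypes, ens, target_class = "POP1", cutoff = 0.5)
  expect_gt(res$lambda_before, 1.1)
  expect_lt(res$lambda_after, res$lambda_before)
  expect_lt(res$n_after, res$n_before)

  # homogeneous cohort: exclusion removes nothing material
  null_sim <- simulate_case_control(1, 150, 800,
                                    case_fraction_per_population = 0.5,
                                    fst = 0, seed = 24)
  # classify against a 2-class model trained on a diverged reference
  preds <- predict_batch(ens, null_sim$genotypes)
  kept <- apply_inclusion_cutoff(preds, "POP1", 1)
  # cutoff = 1 retains only unanimous samples, the subset contract
  unanimous <- vapply(preds$predictions,
                      function(p) isTRUE(p$prob[["POP1"]] == 1), logical(1))
  expect_setequal(kept, names(preds$predictions)[unanimous])
})
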