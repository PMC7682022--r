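test_that("dosage_r2: limits, degenerate convention, arithmetic oracle", {
  x <- c(0, 1, 2, 1, 0)
  expect_equal(dosage_r2(x, x), 1)
  expect_equal(dosage_r2(rep(1, 5), x), 0)
  expect_equal(dosage_r2(x, rep(0, 5)), 0)
  set.seed(71)
  for (i in 1:10) {
    a <- runif(50, 0, 2); b <- runif(50, 0, 2)
    expect_equal(dosage_r2(a, b), oracle_r2(a, b), tolerance = 1e-12)
  }
  # affine invariance (positive slope)
  a <- runif(30); b <- runif(30)
  expect_equal(dosage_r2(3 * a + 1, b), dosage_r2(a, b), tolerance = 1e-12)
  expect_error(dosage_r2(1, 1), "at least 2")
  expect_error(dosage_r2(1:3, 1:4), "equal length")
})

test_that("per-individual accuracy aggregation over replicates", {
  truth <- random_truth(40, runif(30, 0.2, 0.5), seed = 72)
  mask <- rep(c(TRUE, FALSE, FALSE), 10)
  ident <- identical_replicates(truth, mask, K = 3)
  expect_equal(unname(per_individual_r2_summary(ident, truth, "mean")),
               rep(1, 40))
  expect_equal(unname(per_individual_r2_summary(ident, truth, "min")),
               rep(1, 40))
  # mean/min aggregate the per-replicate values
  reps <- emulate_parametric(truth, mask, 0.8, 0.1, K = 4, master_seed = 73)
  M <- per_individual_r2(reps, truth)
  expect_equal(unname(per_individual_r2_summary(reps, truth, "mean")),
               rowMeans(M))
  expect_equal(unname(per_individual_r2_summary(reps, truth, "min")),
               apply(M, 1, min))
  expect_true(all(apply(M, 1, min) <= rowMeans(M)))
})

test_that("minimum accuracy is left-shifted relative to the mean under run noise", {
  truth <- random_truth(400, runif(80, 0.1, 0.5), seed = 74)
  mask <- assign_typed_mask(80, 0.25, rng_seed = 75)
  reps <- emulate_parametric(truth, mask, 0.85, 0.12, K = 6, master_seed = 76)
  mean_r2 <- per_individual_r2_summary(reps, truth, "mean")
  min_r2 <- per_individual_r2_summary(reps, truth, "min")
  expect_lt(median(min_r2), median(mean_r2))
})

test_that("genotype F-score agrees with the confusion-matrix oracle", {
  expect_equal(genotype_fscore(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(genotype_fscore(rep(2, 10), rep(0, 10)), 0)
  # 20-call toy with a known confusion table
  tru <- c(rep(0, 8), rep(1, 7), rep(2, 5))
  imp <- c(rep(0, 6), 1, 1, rep(1, 5), 2, 2, rep(2, 4), 0)
  expect_equal(genotype_fscore(imp, tru), oracle_fscore(imp, tru))
  set.seed(77)
  for (i in 1:20) {
    tru <- sample(0:2, 25, replace = TRUE)
    imp <- sample(0:2, 25, replace = TRUE)
    expect_equal(genotype_fscore(imp, tru), oracle_fscore(imp, tru))
  }
  expect_error(genotype_fscore(c(0, 3), c(0, 1)), "classes")
})

test_that("IQS equals the chance-adjusted agreement of the contingency table", {
  expect_equal(iqs(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  # fixed 3x3 table vs from-scratch kappa
  tru <- c(rep(0, 10), rep(1, 6), rep(2, 4))
  imp <- c(rep(0, 7), 1, 1, 2, rep(1, 5), 0, rep(2, 3), 1)
  expect_equal(iqs(imp, tru), oracle_iqs(imp, tru))
  set.seed(78)
  for (i in 1:20) {
    tru <- sample(0:2, 30, replace = TRUE)
    imp <- sample(0:2, 30, replace = TRUE)
    expect_equal(iqs(imp, tru), oracle_iqs(imp, tru))
  }
  # independence with matched marginals: mean IQS over shuffles ~ 0
  set.seed(79)
  tru <- sample(0:2, 200, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  vals <- replicate(300, iqs(sample(tru), tru))
  expect_lt(abs(mean(vals)), 0.02)
  # degenerate marginals: perfect agreement -> 1
  expect_equal(iqs(rep(1, 5), rep(1, 5)), 1)
  # IQS never exceeds observed agreement
  set.seed(80)
  for (i in 1:10) {
    tru <- sample(0:2, 40, replace = TRUE)
    imp <- sample(0:2, 40, replace = TRUE)
    expect_lte(iqs(imp, tru), mean(imp == tru) + 1e-12)
  }
})

test_that("MAF-binned accuracy: conventions and degradation at low MAF", {
  truth <- random_truth(600, c(0.04, 0.08, 0.3, 0.45), seed = 81)
  mask <- rep(FALSE, 4)
  # noise scaled inversely to MAF: accuracy degrades for rare variants
  set.seed(82)
  noise_sd <- c(0.8, 0.4, 0.05, 0.05)
  reps <- replicate_set(lapply(1:3, function(k) {
    R <- truth$dosages + sapply(noise_sd, function(s) rnorm(600, 0, s))
    pmin(pmax(R, 0), 2)
  }), process = "toy", mask = mask)
  out <- maf_binned_accuracy(reps, truth, bins = c(0, 0.05, 0.1, 0.5))
  r2 <- out$by_bin[out$by_bin$metric == "r2", ]
  rare <- r2[r2$bin == "(0,0.05]", ]
  common <- r2[r2$bin == "(0.1,0.5]", ]
  expect_lt(rare$median, common$median)
  expect_gt(rare$max - rare$min, common$max - common$min)
  # single bin reproduces the unbinned summary
  one <- maf_binned_accuracy(reps, truth, bins = c(0, 0.5))
  r2_all <- out$per_variant$r2
  expect_equal(one$by_bin$median[one$by_bin$metric == "r2"], median(r2_all))
  # boundary variant goes to the lower bin
  expect_equal(as.character(cut(0.05, c(0, 0.05, 0.5), right = TRUE)),
               "(0,0.05]")
  pv <- maf_binned_accuracy(reps, truth, bins = c(0, 0.05, 0.5))$per_variant
  expect_true(all(pv$bin[pv$maf <= 0.05] == "(0,0.05]"))
})

test_that("paired process comparison: degenerate flag and power", {
  a <- runif(30)
  expect_true(paired_process_comparison(a, a)$degenerate)
  # uniform shift of 0.1 at n = 50: p below 1e-6
  set.seed(83)
  a <- runif(50, 0.5, 1)
  res <- paired_process_comparison(a, a - 0.1)
  expect_false(res$degenerate)
  expect_lt(res$p_value, 1e-6)
  # type-I control under symmetric null differences
  set.seed(84)
  p <- replicate(200, {
    d <- rnorm(100)
    paired_process_comparison(d, rep(0, 100))$p_value
  })
  reject <- mean(p < 0.05)
  expect_lt(abs(reject - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("best tag LD: duplicates, independence, nested thresholds", {
  set.seed(85)
  typed <- matrix(rbinom(500 * 4, 2, 0.4), 500)
  untyped <- cbind(typed[, 1], matrix(rbinom(500 * 2, 2, 0.4), 500))
  res <- best_tag_ld(untyped, typed)
  expect_equal(unname(res$best_r2[1]), 1)
  # independent SNPs: best pairwise r2 stays small at n = 500
  expect_lt(max(res$best_r2[2:3]), 0.1)
  expect_true(all(diff(res$fractions) <= 0))
  expect_error(best_tag_ld(untyped, typed[, integer(0)]), "typed")
})
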