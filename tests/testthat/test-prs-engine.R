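test_that("compute_prs evaluates the weighted dosage sum", {
  X <- matrix(c(2, 1, 0), 1, dimnames = list("S1", c("a", "b", "c")))
  m <- data.frame(rsID = c("a", "b", "c"), chr_name = "1",
                  chr_position = 1:3, effect_allele = "G",
                  other_allele = "A", effect_weight = c(0.1, 0.2, 0.3))
  expect_equal(unname(compute_prs(X, m)), 0.4)
  # empty-sum case: all-zero dosages
  X0 <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(compute_prs(X0, m)), rep(0, 5))
  # random matrices match the double-loop oracle exactly
  set.seed(51)
  for (i in 1:5) {
    Xr <- matrix(runif(50, 0, 2), 10, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
    w <- rnorm(5)
    mr <- data.frame(rsID = paste0("v", 1:5), chr_name = "1",
                     chr_position = 1:5, effect_allele = "G",
                     other_allele = "A", effect_weight = w)
    expect_equal(unname(compute_prs(Xr, mr)), oracle_prs(Xr, w))
  }
})

test_that("compute_prs flips dosages when the effect allele is REF and rejects mismatches", {
  truth <- random_truth(20, c(0.3, 0.4), seed = 52)
  m <- data.frame(rsID = c("snp0001", "snp0002"), chr_name = "1",
                  chr_position = c(1000, 2000),
                  effect_allele = c("G", "A"), other_allele = c("A", "G"),
                  effect_weight = c(1, 1))
  s <- compute_prs(truth, m)
  expect_equal(unname(s),
               unname(truth$dosages[, 1] + (2 - truth$dosages[, 2])))
  m$effect_allele[2] <- "T"
  expect_error(compute_prs(truth, m), "neither REF nor ALT")
  m2 <- m; m2$rsID[2] <- "absent"
  expect_error(compute_prs(truth, m2), "absent")
})

test_that("percentile ranks follow the midrank convention", {
  expect_equal(percentile_rank(5, "x"), 50)
  expect_equal(unname(percentile_rank(c(1, 2, 3, 4))),
               c(12.5, 37.5, 62.5, 87.5))
  # three-way tie matches the counting oracle
  s <- c(1, 2, 2, 2, 5)
  expect_equal(unname(percentile_rank(s)), oracle_percentile(s, rep("a", 5)))
  # groups ranked independently
  sc <- c(10, 20, 1, 2)
  anc <- c("A", "A", "B", "B")
  expect_equal(unname(percentile_rank(sc, anc)), c(25, 75, 25, 75))
  expect_error(percentile_rank(c(1, NA)), "NA")
})

test_that("percentile properties: mean 50, translation/scale equivariance", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    s <- sample(rnorm(n - 1), n, replace = TRUE)  # forces some ties
    anc <- sample(c("A", "B"), n, replace = TRUE)
    p <- percentile_rank(s, anc)
    for (g in unique(anc)) expect_equal(mean(p[anc == g]), 50)
    expect_equal(percentile_rank(2.5 * s + 7, anc), p)
  }
})

test_that("tier assignment boundaries follow strict outer inequalities", {
  p <- c(19.999, 20, 80, 80.001)
  expect_equal(as.character(assign_tier(p)),
               c("low", "intermediate", "intermediate", "high"))
  # uniform midrank percentiles split ~20/60/20
  pct <- percentile_rank(seq_len(1000))
  sh <- table(assign_tier(pct)) / 1000
  expect_equal(unname(as.vector(sh)), c(0.2, 0.6, 0.2), tolerance = 0.01)
  # refined "< 5" tier on 100 distinct scores holds exactly 5 members
  expect_identical(sum(percentile_rank(sample(100)) < 5), 5L)
})

test_that("compute_prs is linear in the dosage matrix", {
  set.seed(54)
  A <- matrix(runif(30, 0, 1), 6, 5, dimnames = list(NULL, paste0("v", 1:5)))
  B <- matrix(runif(30, 0, 1), 6, 5, dimnames = list(NULL, paste0("v", 1:5)))
  m <- data.frame(rsID = paste0("v", 1:5), chr_name = "1", chr_position = 1:5,
                  effect_allele = "G", other_allele = "A",
                  effect_weight = rnorm(5))
  expect_equal(compute_prs(A + B, m), compute_prs(A, m) + compute_prs(B, m))
})

test_that("percentile frames rank replicates within their own or the truth distribution", {
  fx <- small_study(seed = 55)
  st <- fx$study
  reps <- emulate_parametric(st$truth, st$mask, 0.85, 0.08, K = 4,
                             master_seed = 56)
  fr <- build_percentile_frame(st$truth, reps, st$model, st$ancestry)
  expect_s3_class(fr, "percentile_frame")
  expect_identical(dim(fr$reps), c(160L, 4L))
  expect_true(all(fr$reps >= 0 & fr$reps <= 100))
  # within-replicate ranking reproduces percentile_rank of that replicate's scores
  s1 <- compute_prs(dosage_matrix(reps$replicates[[1]], st$truth$variants),
                    st$model)
  expect_equal(unname(fr$reps[, 1]), unname(percentile_rank(s1, st$ancestry)))
  # truth-referenced ranking: identical replicates of truth recover the WGS percentiles
  ident <- identical_replicates(st$truth, st$mask, K = 3)
  fr2 <- build_percentile_frame(st$truth, ident, st$model, st$ancestry,
                                rank_within = "truth")
  expect_equal(unname(fr2$reps[, 2]), unname(fr2$wgs))
})
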