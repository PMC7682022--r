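test_that("percentile range table counts thresholds correctly", {
  # identical replicates: everyone in the <=1 row
  fr <- percentile_frame(wgs = c(10, 50, 90),
                         reps = matrix(c(10, 50, 90), 3, 4))
  tab <- percentile_range_table(fr)
  expect_equal(tab$count[tab$row == "<=1"], 3)
  expect_equal(tab$pct[tab$row == "<=1"], 100)
  expect_true(all(tab$count[tab$row != "<=1"] == 0))
  # hand-chosen ranges 0.5, 6, 25
  fr2 <- percentile_frame(wgs = c(50, 50, 50),
                          reps = rbind(c(50, 50.5), c(47, 53), c(40, 65)))
  tab2 <- percentile_range_table(fr2)
  expect_equal(tab2$count, c(1, 2, 2, 1, 1))
  expect_error(percentile_range_table(percentile_frame(50, matrix(50, 1, 1))),
               "K < 2")
})

test_that("range table matches the brute-force counting oracle per stratum", {
  set.seed(61)
  reps <- matrix(runif(1000 * 6, 0, 100), 1000)
  anc <- sample(c("A", "B"), 1000, replace = TRUE)
  fr <- percentile_frame(runif(1000, 0, 100), reps, anc)
  tab <- percentile_range_table(fr)
  for (s in c("A", "B", "all")) {
    sub <- if (s == "all") rep(TRUE, 1000) else anc == s
    expect_equal(tab$count[tab$stratum == s],
                 oracle_range_counts(reps[sub, , drop = FALSE], c(1, 5, 10, 20)))
  }
  # counts non-increasing in the threshold
  for (s in unique(tab$stratum)) {
    cnt <- tab$count[tab$stratum == s][-1]
    expect_true(all(diff(cnt) <= 0))
  }
  # <=1 and >1 partition the stratum
  expect_equal(tab$count[tab$row == "<=1"] + tab$count[tab$row == ">1"],
               as.vector(c(table(anc)[c("A", "B")], 1000)))
})

test_that("deviation by bin: identity, two-replicate case, summaries", {
  # replicates equal to WGS: all deviations zero in every bin
  wgs <- seq(0.5, 99.5, length.out = 200)
  fr <- percentile_frame(wgs, matrix(wgs, 200, 3))
  dv <- deviation_by_bin(fr, n_bins = 10)
  expect_true(all(dv$median == 0))
  expect_true(all(dv$n > 0))
  # one individual, replicates (40, 60), WGS 50: avg = max = 10
  fr2 <- percentile_frame(50, matrix(c(40, 60), 1))
  dv2 <- deviation_by_bin(fr2, n_bins = 4)
  expect_equal(attr(dv2, "avg_dev"), 10)
  expect_equal(attr(dv2, "max_dev"), 10)
  # max deviation >= average deviation always; empty bins flagged not fatal
  fr3 <- percentile_frame(c(5, 7), rbind(c(1, 9), c(4, 12)))
  dv3 <- deviation_by_bin(fr3, n_bins = 10)
  expect_true(all(attr(dv3, "max_dev") >= attr(dv3, "avg_dev")))
  expect_true(any(dv3$n == 0))
  expect_error(deviation_by_bin(fr3, n_bins = 1), "n_bins")
})

test_that("re-classification matrix: diagonal null, hand case, oracle", {
  # identical replicates at uniform percentiles: diagonal ~ 20/60/20
  pct <- percentile_rank(seq_len(500))
  fr <- percentile_frame(pct, matrix(pct, 500, 6))
  tm <- reclassification_matrix(fr)
  expect_equal(unname(diag(tm$primary)), c(20, 60, 20), tolerance = 0.5)
  expect_equal(sum(tm$primary), 100)
  expect_equal(sum(tm$primary) - sum(diag(tm$primary)), 0)
  # 1 individual, K = 2, percentiles 19 and 21 (mean 20 -> intermediate)
  fr2 <- percentile_frame(20, matrix(c(19, 21), 1))
  tm2 <- reclassification_matrix(fr2)
  expect_equal(tm2$primary["low", "intermediate"], 50)
  expect_equal(tm2$primary["intermediate", "intermediate"], 50)
  # random frame equals the explicit pair-loop oracle
  set.seed(62)
  reps <- matrix(runif(300 * 5, 0, 100), 300)
  fr3 <- percentile_frame(runif(300, 0, 100), reps)
  tm3 <- reclassification_matrix(fr3)
  expect_equal(unclass(tm3$primary), oracle_tier_matrix(reps, c(20, 80)),
               ignore_attr = TRUE)
})

test_that("refined-tier re-classification rates and Wald intervals", {
  # all replicates equal WGS: 0% (0-0) in every tier
  wgs <- percentile_rank(seq_len(400))
  fr <- percentile_frame(wgs, matrix(wgs, 400, 6))
  hr <- highrisk_reclassification(fr)
  expect_true(all(hr$rate == 0))
  expect_true(all(hr$ci_lo == 0 & hr$ci_hi == 0))
  # 4-member tier with 1 re-classified: 25% +/- 42.4
  fr2 <- percentile_frame(c(1, 2, 3, 4, 60, 70),
                          reps = rbind(c(50, 60), c(1, 2), c(2, 3), c(3, 4),
                                       c(60, 60), c(70, 70)))
  hr2 <- highrisk_reclassification(fr2,
                                   data.frame(direction = "<", cut = 5))
  expect_equal(hr2$rate, 25)
  expect_equal(hr2$ci_hi - hr2$rate, 1.96 * sqrt(25 * 75 / 4))
  expect_equal(hr2$ci_lo, 25 - 1.96 * sqrt(25 * 75 / 4))
  # empty tier reported as NA
  hr3 <- highrisk_reclassification(fr2,
                                   data.frame(direction = ">", cut = 99))
  expect_true(is.na(hr3$rate))
  # random frames match the counting oracle
  set.seed(63)
  reps <- matrix(runif(500 * 6, 0, 100), 500)
  wgs3 <- runif(500, 0, 100)
  fr4 <- percentile_frame(wgs3, reps)
  hr4 <- highrisk_reclassification(fr4)
  for (i in seq_len(nrow(hr4))) {
    dir <- substr(hr4$tier[i], 1, 1)
    cut <- as.numeric(substring(hr4$tier[i], 2))
    expect_equal(hr4$rate[i], oracle_highrisk_rate(wgs3, reps, dir, cut))
  }
  expect_true(all(hr4$rate <= 100))
})
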