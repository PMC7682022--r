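test_that("ancestral frequency draws respect the MAF range and reject bad input", {
  af <- draw_ancestral_frequencies(1000, c(0.01, 0.5), rng_seed = 1)
  expect_length(af, 1000)
  maf <- pmin(af, 1 - af)
  expect_true(all(maf >= 0.01 & maf <= 0.5))
  expect_true(all(af > 0 & af < 1))
  expect_error(draw_ancestral_frequencies(5, c(0.5, 0.5)), "maf_range")
  expect_error(draw_ancestral_frequencies(0, c(0.01, 0.5)), "positive")
  # uniform MAF on (0.05, 0.5): mean 0.275, sd of mean = width/sqrt(12 n)
  af2 <- draw_ancestral_frequencies(10000, c(0.05, 0.5), rng_seed = 2)
  se <- 0.45 / sqrt(12 * 10000)
  expect_lt(abs(mean(pmin(af2, 1 - af2)) - 0.275), 3 * se)
  expect_identical(draw_ancestral_frequencies(50, c(0.05, 0.5), 3),
                   draw_ancestral_frequencies(50, c(0.05, 0.5), 3))
})

test_that("Balding-Nichols divergence has the stated mean and variance", {
  p <- rep(0.5, 10000)
  expect_identical(derive_population_frequencies(p, 0)$freq, p)
  pf <- derive_population_frequencies(p, 0.15, rng_seed = 4)
  v <- var(pf$freq)
  expect_lt(abs(v - 0.15 * 0.25) / (0.15 * 0.25), 0.10)
  expect_lt(abs(mean(pf$freq) - 0.5), 0.01)
  # boundary fst accepted, frequencies stay in [0, 1]
  pb <- derive_population_frequencies(rep(0.3, 100), 0.99, rng_seed = 5)
  expect_true(all(pb$freq >= 0 & pb$freq <= 1))
  expect_error(derive_population_frequencies(p, 1), "fst")
  expect_error(derive_population_frequencies(p, -0.01), "fst")
})

test_that("fst recovery: empirical Var/(p(1-p)) estimates fst within 10%", {
  for (fst in c(0.05, 0.15)) {
    p <- draw_ancestral_frequencies(20000, c(0.2, 0.5), rng_seed = 6)
    pf <- derive_population_frequencies(p, fst, rng_seed = 7)
    est <- mean((pf$freq - p)^2 / (p * (1 - p)))
    expect_lt(abs(est - fst) / fst, 0.10)
  }
})

test_that("haplotype panel: frequencies, LD structure, and minimal panel", {
  p <- rep(0.4, 400)
  # block_length 1: iid draws, frequency within binomial error, LD ~ 0
  pan <- simulate_haplotype_panel(p, 500, block_length = 1, rng_seed = 8)
  f <- colMeans(pan$haplotypes)
  se <- sqrt(0.4 * 0.6 / 500)
  expect_lt(max(abs(f - 0.4)), 5 * se)
  r2 <- cor(pan$haplotypes[, 1], pan$haplotypes[, 2])^2
  expect_lt(r2, 0.05)
  expect_true(all(diff(pan$positions) > 0))
  # strong copying inside a 2-variant block: r2 > 0.5 on average
  set.seed(9)
  r2s <- replicate(50, {
    pan2 <- simulate_haplotype_panel(c(0.5, 0.5), 200, block_length = 2,
                                     rng_seed = sample.int(1e6, 1),
                                     n_founders = 2, mutation_rate = 0.001)
    h <- pan2$haplotypes
    if (sd(h[, 1]) == 0 || sd(h[, 2]) == 0) NA else cor(h[, 1], h[, 2])^2
  })
  expect_gt(mean(r2s, na.rm = TRUE), 0.5)
  # minimal panel
  expect_silent(pan3 <- simulate_haplotype_panel(c(0.5, 0.2), 2, 1, rng_seed = 1))
  expect_identical(dim(pan3$haplotypes), c(2L, 2L))
  expect_error(simulate_haplotype_panel(p, 1, 1), "n_haplotypes")
})

test_that("cohort simulation: dosages are haplotype sums and sizes are honoured", {
  pan <- simulate_haplotype_panel(rep(0.3, 20), 60, block_length = 5,
                                  rng_seed = 10)
  pan$population <- rep(c("EUR", "AFR"), each = 30)
  # study-sized draw: 1447 + 239 = 1686 individuals
  cohort <- simulate_cohort(pan, c(EUR = 1447L, AFR = 239L), rng_seed = 11)
  expect_identical(nrow(cohort$truth$dosages), 1686L)
  expect_equal(as.integer(table(cohort$ancestry)[c("EUR", "AFR")]),
               c(1447L, 239L), ignore_attr = TRUE)
  expect_true(all(cohort$truth$dosages %in% 0:2))
  # dosage equals the sum of the retained haplotype rows
  h <- cohort$haplotypes
  expect_equal(unname(h[seq(1, nrow(h), 2), ] + h[seq(2, nrow(h), 2), ]),
               unname(cohort$truth$dosages))
  # dosage mean ~ 2 * panel pool frequency per population
  fpan <- colMeans(pan$haplotypes[pan$population == "EUR", ])
  fcoh <- colMeans(cohort$truth$dosages[cohort$ancestry == "EUR", ]) / 2
  se <- sqrt(fpan * (1 - fpan) / (2 * 1447))
  expect_true(all(abs(fcoh - fpan) < 4 * pmax(se, 1e-3)))
  expect_error(simulate_cohort(pan, c(SAS = 5L)), "absent")
})

test_that("PRS model generation: sizes, high-weight planting, determinism", {
  m <- generate_prs_model(161, rng_seed = 12)
  expect_s3_class(m, "prs_model")
  expect_identical(nrow(m), 161L)
  expect_false(any(m$effect_allele == m$other_allele))
  expect_false(anyDuplicated(m$rsID) > 0)
  # no high-weight variants: all weights on the base scale
  m0 <- generate_prs_model(500, weight_scale = 0.1, n_high_weight = 0,
                           rng_seed = 13)
  expect_lt(max(abs(m0$effect_weight)), 0.1 * 5)
  # a 10x planted SNP dominates percent variance explained at equal freqs
  mh <- generate_prs_model(30, weight_scale = 0.1, n_high_weight = 1,
                           high_weight_multiplier = 10, rng_seed = 14)
  hi <- which.max(abs(mh$effect_weight))
  truth <- random_truth(2000, rep(0.5, 30), seed = 15)
  pve <- percent_variance_explained(mh, truth)
  expect_identical(unname(which.max(pve)), hi)
  expect_true(all(pve[hi] > pve[-hi]))
  expect_error(generate_prs_model(5, n_high_weight = 6), "n_high_weight")
})

test_that("typed mask: size, bounds, determinism", {
  m <- assign_typed_mask(161, 38 / 161, rng_seed = 16)
  expect_identical(sum(m), 38L)
  expect_identical(sum(!m), 123L)
  expect_true(all(assign_typed_mask(10, 1, 1)))
  expect_identical(assign_typed_mask(100, 0.25, 17),
                   assign_typed_mask(100, 0.25, 17))
  expect_error(assign_typed_mask(100, 0.001), "zero typed")
  expect_error(assign_typed_mask(100, 0), "fraction_typed")
})
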